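# screcon

Reconstruction of cis-regulatory element (CRE) activity from sparse
single-cell ATAC-seq data, by borrowing strength from a compendium of bulk
DNase-seq/ATAC-seq samples.

## The problem

scATAC-seq measures chromatin accessibility in single cells, but a cell
yields only a few thousand to a hundred thousand reads spread over hundreds
of thousands of regulatory elements: per-element counts are near-binary and
mostly zero. Quantitative, element-level activity estimates therefore cannot
be obtained from one cell's reads alone. This package reconstructs a
continuous activity for every known CRE by combining three sources of
information:

1. **Locus effects from bulk data.** Each 200-bp CRE bin has a
   cell-type-independent baseline mean *m_i* and variability *s_i*, learned
   once from a diverse bulk regulome compendium.
2. **Co-activation.** CREs that move together across bulk cell types are
   clustered; CREs in a cluster share one cell-specific activity.
3. **Similar cells.** Cells are clustered and pooled into pseudo-cells
   before reconstruction.

## The model

For cell (or pseudo-cell) *j* with library factor *L_j* (total reads / 10^8),
the observed count of CRE *i* follows

    y_ij ~ Poisson(L_j * mu_sc_ij)
    log(mu_sc_ij) = h_j(log mu_ij)          # monotone technical bias
    log(mu_ij)    = m_i + s_i * delta_ij    # locus effects x cell activity
    delta_j       = X beta_j,   beta_kj ~ N(0, 1)

where **X** is the CRE-cluster membership matrix at resolution *K*.
The locus effects come from the bulk model `y ~ Poisson(L * exp(m + s*delta))`
with `delta ~ N(0,1)`, estimated in closed form by the method of moments.
The bias function *h_j* is a monotone I-spline fit by constrained maximum
likelihood at "low-variability" CREs (nearly constant across cell types, so
their single-cell activity is known up to *h_j*). Cluster activities
`beta` are posterior modes under the N(0,1) prior, and the resolution *K*
is chosen per cell by cross-validation: the level with the largest median
held-out Poisson log-likelihood wins. Reconstructed activities
`mu = exp(m + s * X beta)` are extended to non-catalog bins with
gradient-boosted regression trees, and peaks are called by a
moving-average empirical-FDR procedure.

## Worked example

```r
library(screcon)

# a synthetic world: 2000 bins, 80 bulk samples, 10 CRE clusters
sim  <- simulate_compendium(n_bins = 2000, n_samples = 80,
                            n_clusters = 10, seed = 901)
comp <- build_compendium(sim$counts, stage1_k = 5000, seed = 902)
length(comp$catalog$bin_ids)
#> [1] 120

# a 2-type mixture of 200 cells at 1e5 reads/cell
sc  <- simulate_scatac(sim$truth, n_cells_per_type = c(100, 100),
                       reads_per_cell = 1e5, seed = 903)
res <- reconstruct_population(sc$counts, comp, seed = 904)
res$clustering$n_clusters
#> [1] 2
adjusted_rand_index(res$clustering$labels, sc$labels)
#> [1] 1
sapply(res$fits, function(f) f$cv$chosen_K)
#> [1] 30  7
```

The two cell types are recovered exactly (adjusted Rand index 1), and the
cross-validation picked different resolutions for the two pseudo-cells
(30 and 7 CRE clusters). Reconstructed log-activities track each type's
truth closely — in this run the Pearson correlation with the matching
type's true `log mu` is 0.98 and 0.96, against 0.43 and 0.35 for the wrong
type — and the reconstructed differential activity between the two clusters
correlates 0.94 with the true differential. Genome-wide tracks, peaks and
TFBS rankings follow from:

```r
fit   <- res$fits[[1]]
track <- predict_noncre_bins(fit$pseudo_cell$counts, fit$pseudo_cell$L,
                             comp$effects_genome, fit$recon,
                             comp$catalog$bin_ids, comp$index)
peaks <- call_peaks(track, seed = 1)
```

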