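# Synthetic-data generators drawn from the package's own generative model,
# so every stage can be tested closed-loop against known ground truth.

rtruncnorm1 <- function(n, mean, sd, lower, upper) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(n, mean, sd)
    out <- c(out, x[x >= lower & x <= upper])
  }
  out[seq_len(n)]
}

bias_function <- function(spec = c("identity", "affine", "smooth")) {
  spec <- match.arg(spec)
  switch(spec,
         identity = identity,
         affine = function(x) 0.5 + 0.8 * x,
         smooth = function(x) x - 0.3 * tanh(x - 1))
}

#' Simulate a bulk regulome compendium
#'
#' Bins live on one chromosome of `n_bins * bin_width` bp. A fraction of
#' bins are planted CREs with locus effects `m ~ N(0.5, 1)` truncated to
#' [-2, 4] and `s ~ U(0.2, 1.2)`; CREs are grouped into clusters, and within
#' a cluster all CREs share one `delta ~ N(0, 1)` per sample. Counts are
#' `y ~ Poisson(L * exp(m + s * delta))`; non-CRE background bins have a low
#' constant rate.
#'
#' @param n_bins number of genome bins (default 2000).
#' @param n_samples number of bulk samples (default 50).
#' @param n_clusters number of planted CRE clusters (default 10).
#' @param cre_frac fraction of bins that are CREs (default 0.3).
#' @param library_sizes per-sample `L_j` (default `U(0.5, 2)`).
#' @param m_mean,m_sd,m_range parameters of the truncated-normal `m`.
#' @param s_range range of the uniform `s`.
#' @param bg_mu background Poisson rate per unit library factor
#'   (default 0.05).
#' @param bin_width bin width in bp (default 200).
#' @param seed RNG seed.
#' @return list with `counts` (a `bin_count_matrix`) and `truth`
#'   (a `simulation_truth`: index, `cre_bins`, `m`, `s`, `cluster`,
#'   `delta` (clusters x samples), `bg_mu`, `seed`).
#' @export
simulate_compendium <- function(n_bins = 2000, n_samples = 50,
                                n_clusters = 10, cre_frac = 0.3,
                                library_sizes = NULL, m_mean = 0.5,
                                m_sd = 1, m_range = c(-2, 4),
                                s_range = c(0.2, 1.2), bg_mu = 0.05,
                                bin_width = 200, seed = 1) {
  set.seed(seed)
  index <- segment_genome(c(chr1 = n_bins * bin_width), bin_width)
  L <- library_sizes %||% runif(n_samples, 0.5, 2)
  n_samples <- length(L)
  n_cre_target <- max(n_clusters, round(cre_frac * n_bins))
  # CREs come as small contiguous sites (1-3 bins), mirroring the multi-bin
  # footprint of real open-chromatin sites; bins of a site share a cluster
  n_sites <- max(n_clusters, ceiling(n_cre_target / 2))
  starts <- sort(sample.int(n_bins - 2, n_sites))
  widths <- sample(1:3, n_sites, replace = TRUE)
  site_of <- integer(n_bins)
  for (k in seq_len(n_sites)) {
    b <- starts[k]:min(starts[k] + widths[k] - 1L, n_bins)
    site_of[b[site_of[b] == 0]] <- k
  }
  cre_bins <- which(site_of > 0)
  if (length(cre_bins) > n_cre_target) {
    keep_sites <- site_of[cre_bins][seq_len(n_cre_target)]
    cre_bins <- cre_bins[site_of[cre_bins] %in% keep_sites]
  }
  n_cre <- length(cre_bins)
  m <- rtruncnorm1(n_cre, m_mean, m_sd, m_range[1], m_range[2])
  s <- runif(n_cre, s_range[1], s_range[2])
  site_cluster <- rep_len(seq_len(n_clusters), n_sites)[sample.int(n_sites)]
  cluster <- site_cluster[site_of[cre_bins]]
  delta <- matrix(rnorm(n_clusters * n_samples), n_clusters, n_samples)
  counts <- matrix(rpois(n_bins * n_samples,
                         rep(L, each = n_bins) * bg_mu),
                   n_bins, n_samples)
  mu_cre <- exp(m + s * delta[cluster, , drop = FALSE])
  counts[cre_bins, ] <- rpois(n_cre * n_samples,
                              sweep(mu_cre, 2, L, "*"))
  truth <- structure(list(index = index, cre_bins = cre_bins, m = m, s = s,
                          cluster = cluster, delta = delta, bg_mu = bg_mu,
                          n_clusters = n_clusters, seed = seed),
                     class = "simulation_truth")
  list(counts = bin_count_matrix(counts, index, library_factors = L),
       truth = truth)
}

#' Simulate single-cell ATAC-seq data from a compendium truth
#'
#' Each cell type draws one activity `beta ~ N(0, 1)` per CRE cluster;
#' within a type every cell shares `mu = exp(m + s * (X beta))` at CRE bins
#' (background bins keep the background rate). The technical bias distorts
#' this to `mu_sc = exp(h(log mu))`, the library factor is set so the
#' expected total read count equals `reads_per_cell`, and counts are drawn
#' independently per cell as `y ~ Poisson(L * mu_sc)`.
#'
#' @param truth a `simulation_truth` from [simulate_compendium()].
#' @param n_cells_per_type integer vector, cells per type.
#' @param reads_per_cell expected total reads per cell (default 1e4).
#' @param bias `"identity"`, `"affine"` or `"smooth"` monotone bias.
#' @param seed RNG seed.
#' @return list with `counts` (bins x cells), `labels` (cell type per
#'   cell), `L` (per-cell library factors), `betas` (clusters x types),
#'   `mu` (bins x types, bulk-scale truth), `bias`.
#' @export
simulate_scatac <- function(truth, n_cells_per_type = c(100, 100),
                            reads_per_cell = 1e4,
                            bias = c("identity", "affine", "smooth"),
                            seed = 1) {
  bias <- match.arg(bias)
  h <- bias_function(bias)
  set.seed(seed)
  n_types <- length(n_cells_per_type)
  n_bins <- truth$index$n_bins
  betas <- matrix(rnorm(truth$n_clusters * n_types), truth$n_clusters,
                  n_types)
  mu <- matrix(truth$bg_mu, n_bins, n_types)
  for (k in seq_len(n_types))
    mu[truth$cre_bins, k] <- exp(truth$m + truth$s *
                                   betas[truth$cluster, k])
  mu_sc <- exp(h(log(mu)))
  labels <- rep(seq_len(n_types), n_cells_per_type)
  n_cells <- length(labels)
  L <- reads_per_cell / colSums(mu_sc)[labels]
  counts <- matrix(rpois(n_bins * n_cells,
                         mu_sc[, labels] * rep(L, each = n_bins)),
                   n_bins, n_cells)
  list(counts = counts, labels = labels, L = L, betas = betas, mu = mu,
       bias = bias)
}

#' Build a CRE hierarchy from the planted cluster structure
#'
#' Produces nested levels around the true partition: coarser levels group
#' consecutive true clusters, finer levels split each true cluster evenly.
#' Useful for resolution-selection tests where the candidate set must
#' contain the truth.
#'
#' @param truth a `simulation_truth`.
#' @param coarse integer vector of coarser cluster counts (divisors of the
#'   true count work best).
#' @param split_factors integer vector; each true cluster is split into
#'   this many subclusters for a finer level.
#' @return a `cre_hierarchy` over the CRE bins (rows follow
#'   `truth$cre_bins`).
#' @export
truth_hierarchy <- function(truth, coarse = c(2, 5), split_factors = 5) {
  cl <- truth$cluster
  cols <- list()
  for (K in coarse)
    cols[[paste0("c", K)]] <- ((cl - 1L) %% K) + 1L
  cols[["true"]] <- cl
  for (f in split_factors) {
    sub <- integer(length(cl))
    for (k in unique(cl)) {
      idx <- which(cl == k)
      sub[idx] <- rep_len(seq_len(min(f, length(idx))), length(idx))
    }
    cols[[paste0("f", f)]] <- as.integer(factor(paste(cl, sub)))
  }
  cre_hierarchy(do.call(cbind, cols))
}

#' Write a self-contained synthetic fixture suite
#'
#' Simulates a compendium and a two-type cell population, and writes
#' everything as plain text: compendium counts (MTX + bin BED + samples),
#' per-cell counts (MTX), cell labels (TSV), and the ground truth (JSON).
#' The `"tiny"` scale runs the full pipeline in well under a minute.
#'
#' @param dir output directory (created if needed).
#' @param scale `"tiny"` or `"small"`.
#' @param seed RNG seed.
#' @return `dir`, invisibly; the simulated objects as attribute `"objects"`.
#' @export
make_fixture_suite <- function(dir, scale = c("tiny", "small"), seed = 1) {
  scale <- match.arg(scale)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- if (scale == "tiny")
    list(n_bins = 400, n_samples = 12, n_clusters = 4, cells = c(15, 15),
         reads = 2000) else
    list(n_bins = 2000, n_samples = 40, n_clusters = 10, cells = c(60, 60),
         reads = 5000)
  sim <- simulate_compendium(n_bins = p$n_bins, n_samples = p$n_samples,
                             n_clusters = p$n_clusters, seed = seed)
  sc <- simulate_scatac(sim$truth, n_cells_per_type = p$cells,
                        reads_per_cell = p$reads, seed = seed + 1)
  write_count_matrix(sim$counts, file.path(dir, "compendium"))
  Matrix::writeMM(methods::as(Matrix::Matrix(sc$counts, sparse = TRUE),
                              "generalMatrix"),
                  file.path(dir, "cells.mtx"))
  write.table(data.frame(cell = seq_along(sc$labels), type = sc$labels,
                         L = sprintf("%.17g", sc$L)),
              file.path(dir, "cells.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  truth <- sim$truth
  jsonlite::write_json(
    list(scale = scale, seed = seed, cre_bins = truth$cre_bins,
         m = truth$m, s = truth$s, cluster = truth$cluster,
         bg_mu = truth$bg_mu, betas = sc$betas, bias = sc$bias),
    file.path(dir, "truth.json"), digits = NA, auto_unbox = TRUE)
  out <- invisible(dir)
  attr(out, "objects") <- list(compendium = sim, cells = sc)
  out
}
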