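# Everything learned from the bulk regulome compendium: normalization,
# signal-bin detection, the CRE catalog, locus effects (method of moments on
# the Poisson-lognormal model), the low-variability CRE set, multi-resolution
# CRE clustering, and the variance-explained summary.

#' Library-size normalize and log2-transform counts
#'
#' Computes `ytilde = log2(y / L + 1)` per entry, the normalized activity used
#' for signal-bin detection, CRE clustering and cell features.
#'
#' @param bcm a `bin_count_matrix`.
#' @return numeric matrix, bins x samples.
#' @export
normalize_counts <- function(bcm) {
  L <- bcm$library_factors
  bad <- L == 0 & colSums(bcm$counts) > 0
  if (any(bad)) stop("zero library factor with nonzero counts")
  L[L == 0] <- 1   # all-zero sample: column stays all-zero
  log2(sweep(bcm$counts, 2, L, "/") + 1)
}

#' Detect signal bins in bulk samples
#'
#' Bin i is a signal bin in sample j iff (1) raw count `y >= 10`,
#' (2) normalized `ytilde >= 5`, and (3) `ytilde` is at least
#' `species_factor` times (5 human, 3 mouse) the background, defined as the
#' mean normalized signal over the 100-kb window centered on the bin,
#' excluding the bin itself and masked bins, clipped at chromosome ends. A
#' zero-background window satisfies (3) for any positive `ytilde`. Masked and
#' trailing partial bins are never flagged.
#'
#' @param bcm a `bin_count_matrix`.
#' @param normalized matrix from [normalize_counts()] (recomputed if NULL).
#' @param species_factor background fold cutoff (default 5; use 3 for mouse).
#' @param bg_window_bp width of the background window in bp (default 1e5).
#' @return logical matrix, bins x samples.
#' @export
detect_signal_bins <- function(bcm, normalized = NULL, species_factor = 5,
                               bg_window_bp = 1e5) {
  index <- bcm$index
  if (bg_window_bp < index$bin_width)
    stop("background window smaller than bin width")
  if (is.null(normalized)) normalized <- normalize_counts(bcm)
  hw <- max(1L, as.integer(bg_window_bp %/% (2L * index$bin_width)))
  un <- as.numeric(!index$masked)
  chrom_f <- factor(index$bins$chrom, levels = unique(index$bins$chrom))
  sig <- matrix(FALSE, nrow(normalized), ncol(normalized))
  for (ch in levels(chrom_f)) {
    rows <- which(chrom_f == ch)
    n <- length(rows)
    y <- bcm$counts[rows, , drop = FALSE]
    yt <- normalized[rows, , drop = FALSE]
    u <- un[rows]
    # windowed sums via cumulative sums, window [i-hw, i+hw]
    lo <- pmax(seq_len(n) - hw, 1L); hi <- pmin(seq_len(n) + hw, n)
    cs <- apply(rbind(0, yt * u), 2, cumsum)
    wsum <- cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]
    cu <- cumsum(c(0, u))
    wcnt <- cu[hi + 1L] - cu[lo]
    bgsum <- wsum - yt * u
    bgcnt <- pmax(wcnt - u, 0)
    bg <- bgsum / ifelse(bgcnt > 0, bgcnt, 1)
    bg[bgcnt == 0, ] <- 0
    sig[rows, ] <- (y >= 10) & (yt >= 5) & (yt >= species_factor * bg)
  }
  sig[index$masked | index$partial, ] <- FALSE
  dimnames(sig) <- list(NULL, bcm$sample_ids)
  sig
}

#' Compile the CRE catalog
#'
#' A bin is a known CRE iff it is a signal bin in at least one compendium
#' sample.
#'
#' @param signal_bins logical matrix from [detect_signal_bins()].
#' @return A `cre_catalog`: list with `bin_ids` (row indices in genome order)
#'   and `support` (logical matrix, catalog CREs x samples).
#' @export
compile_cres <- function(signal_bins) {
  ids <- which(rowSums(signal_bins) > 0)
  structure(list(bin_ids = ids,
                 support = signal_bins[ids, , drop = FALSE]),
            class = "cre_catalog")
}

#' Fraction of novel CREs contributed by a new sample
#'
#' Computed as |new signal bins not in the catalog| divided by the size of
#' the updated catalog (catalog union new bins).
#'
#' @param catalog_bins integer vector of catalog bin ids.
#' @param new_bins integer vector of the new sample's signal-bin ids.
#' @return fraction in [0, 1].
#' @export
catalog_saturation <- function(catalog_bins, new_bins) {
  u <- union(catalog_bins, new_bins)
  if (length(u) == 0) return(0)
  length(setdiff(new_bins, catalog_bins)) / length(u)
}

#' Method-of-moments locus effects
#'
#' Under the bulk model `y ~ Poisson(L * exp(m + s*delta))`,
#' `delta ~ N(0,1)`, matching the first two moments of `y/L` gives closed
#' forms: `s = sqrt(log(r))` with
#' `r = (mean((y/L)^2) - mean(y/L^2)) / mean(y/L)^2`, and
#' `m = log(mean(y/L)) - s^2/2`. When `r < 1` (or any intermediate is
#' non-finite) the degenerate branch sets `s = 0`, `m = log(mean(y/L))` and
#' flags the row. All-zero rows get `m = -Inf` (excluded downstream).
#'
#' @param counts integer matrix, bins (or CREs) x samples, J >= 2 columns.
#' @param library_factors per-sample `L_j > 0`.
#' @return data.frame with columns `m`, `s` (natural-log scale), `fallback`.
#' @export
estimate_locus_effects <- function(counts, library_factors) {
  counts <- as.matrix(counts)
  L <- library_factors
  stopifnot(ncol(counts) >= 2, length(L) == ncol(counts), all(L > 0))
  J <- ncol(counts)
  yL <- sweep(counts, 2, L, "/")
  m1 <- rowSums(yL) / J
  m2 <- rowSums(yL^2) / J
  corr <- rowSums(sweep(counts, 2, L^2, "/")) / J
  ratio <- (m2 - corr) / m1^2
  fallback <- !is.finite(ratio) | ratio < 1
  s <- sqrt(log(pmax(ratio, 1)))
  s[fallback | !is.finite(s)] <- 0
  fallback <- fallback | !is.finite(s)
  m <- log(m1) - s^2 / 2        # log(0) = -Inf sentinel for all-zero rows
  fallback[m1 == 0] <- TRUE
  nz <- m1 == 0
  if (any(nz)) s[nz] <- 0
  data.frame(m = m, s = s, fallback = fallback)
}

#' Select the low-variability CRE set
#'
#' CREs are stratified into `n_strata` strata by the 10%,...,90% quantiles of
#' baseline mean `m`; within each stratum the `per_stratum` CREs with the
#' smallest baseline SD `s` are taken (stable tie-break by genome order).
#' These near-constant CREs anchor the technical-bias fit.
#'
#' @param effects data.frame from [estimate_locus_effects()] (catalog rows).
#' @param n_strata number of strata (default 10).
#' @param per_stratum CREs kept per stratum (default 1000).
#' @return data.frame with columns `cre` (row index into `effects`) and
#'   `stratum`.
#' @export
select_low_variability <- function(effects, n_strata = 10,
                                   per_stratum = 1000) {
  ok <- which(is.finite(effects$m))
  if (length(ok) < n_strata) stop("fewer CREs than strata")
  m <- effects$m[ok]; s <- effects$s[ok]
  qs <- quantile(m, probs = seq_len(n_strata - 1) / n_strata, names = FALSE)
  stratum <- findInterval(m, qs) + 1L
  picks <- lapply(seq_len(n_strata), function(st) {
    idx <- which(stratum == st)
    idx <- idx[order(s[idx], idx)]            # stable: (s, genome order)
    idx[seq_len(min(per_stratum, length(idx)))]
  })
  sel <- unlist(picks)
  out <- data.frame(cre = ok[sel], stratum = rep(seq_len(n_strata),
                                                 lengths(picks)))
  out[order(out$cre), , drop = FALSE]
}

# ---------------------------------------------------------------------------
# Multi-resolution CRE clustering
# ---------------------------------------------------------------------------

standardize_rows <- function(x) {
  mu <- rowMeans(x)
  sd <- sqrt(rowSums((x - mu)^2) / max(ncol(x) - 1, 1))
  z <- (x - mu) / ifelse(sd > 0, sd, 1)
  z[sd == 0, ] <- 0          # degenerate rows kept (aligned), zeroed
  z
}

#' Halving sequence of coarse resolution levels
#'
#' Repeatedly halves (floor) the stage-1 cluster count; with the default
#' 5000 stage-1 clusters and 5 halvings this yields 5000, 2500, 1250, 625,
#' 312, 156.
#'
#' @param k0 starting cluster count.
#' @param n_halvings number of halvings (default 5).
#' @return integer vector, decreasing, starting at `k0`.
#' @export
coarse_levels <- function(k0, n_halvings = 5) {
  out <- integer(n_halvings + 1)
  out[1] <- as.integer(k0)
  for (i in seq_len(n_halvings)) out[i + 1] <- out[i] %/% 2L
  out <- out[out >= 1L]
  unique(out)
}

#' Construct a CRE hierarchy from explicit assignments
#'
#' @param assignment integer matrix, CREs x levels, each column a partition.
#' @return A `cre_hierarchy` with columns ordered by increasing cluster
#'   count K.
#' @export
cre_hierarchy <- function(assignment) {
  assignment <- as.matrix(assignment)
  ks <- apply(assignment, 2, function(v) length(unique(v)))
  o <- order(ks)
  structure(list(levels = as.integer(ks[o]),
                 assignment = assignment[, o, drop = FALSE]),
            class = "cre_hierarchy")
}

#' Cluster CREs at multiple resolution levels
#'
#' Three-stage procedure on row-standardized normalized profiles.
#' Stage 1: K-means (Euclidean, Lloyd, 10 restarts) into `stage1_k` clusters
#' (capped at the CRE count). Stage 2: complete-linkage hierarchical
#' clustering of the standardized cluster-mean profiles, cut at the halving
#' sequence of levels (5000, 2500, ..., 156 at full scale). Stage 3: within
#' each stage-1 cluster, a complete-linkage tree is cut into 2, 4, 8, ...
#' subclusters down to singletons; the global fine level at depth d assigns
#' every stage-1 cluster min(2^d, size) subclusters, so
#' K(d) = sum_c min(2^d, size_c).
#'
#' @param normalized matrix of normalized activities, catalog CREs x samples.
#' @param stage1_k stage-1 cluster count (default 5000).
#' @param seed RNG seed for K-means.
#' @return A `cre_hierarchy`; stage-1 labels in `$stage1`.
#' @export
cluster_cres <- function(normalized, stage1_k = 5000, seed = 1) {
  z <- standardize_rows(as.matrix(normalized))
  n <- nrow(z)
  k1 <- min(stage1_k, n)
  ndist <- nrow(unique(z))
  k1 <- min(k1, ndist)
  set.seed(seed)
  s1 <- if (k1 < n) {
    kmeans(z, centers = k1, nstart = 10, iter.max = 300,
           algorithm = "Lloyd")$cluster
  } else seq_len(n)
  k1 <- length(unique(s1))
  cols <- list()
  # Stage 2: coarse levels from standardized cluster means
  means <- rowsum(normalized, s1) / as.vector(table(s1))
  meanz <- standardize_rows(means)
  if (k1 > 1) {
    tree2 <- hclust(dist(meanz), method = "complete")
    for (K in coarse_levels(k1)) {
      lab <- cutree(tree2, k = K)[s1]
      cols[[paste0("c", K)]] <- as.integer(lab)
    }
  } else cols[["c1"]] <- rep(1L, n)
  # Stage 3: fine levels by per-cluster subdivision depth
  sizes <- as.vector(table(s1))
  maxd <- ceiling(log2(max(sizes)))
  if (maxd >= 1) {
    sub <- matrix(1L, n, maxd)    # subcluster label per CRE per depth
    for (cl in seq_len(k1)) {
      members <- which(s1 == cl)
      if (length(members) == 1) next
      tr <- hclust(dist(z[members, , drop = FALSE]), method = "complete")
      for (d in seq_len(maxd)) {
        kk <- min(2^d, length(members))
        sub[members, d] <- cutree(tr, k = kk)
      }
    }
    for (d in seq_len(maxd)) {
      lab <- as.integer(factor(paste(s1, sub[, d])))
      cols[[paste0("f", d)]] <- lab
    }
  }
  mat <- do.call(cbind, cols)
  ks <- apply(mat, 2, function(v) length(unique(v)))
  mat <- mat[, !duplicated(ks), drop = FALSE]
  h <- cre_hierarchy(mat)
  h$stage1 <- s1
  h
}

#' Proportion of compendium variance explained by the mean profile
#'
#' `J * sum_i (a_i - abar)^2 / sum_ij (ytilde_ij - ybar)^2`, where `a` is the
#' per-CRE mean across samples. Returns 0 when the total sum of squares is 0.
#'
#' @param normalized matrix, CREs x samples.
#' @param profile optional per-CRE mean (defaults to `rowMeans(normalized)`).
#' @return fraction in [0, 1].
#' @export
variance_explained <- function(normalized, profile = NULL) {
  a <- profile %||% rowMeans(normalized)
  tot <- sum((normalized - mean(normalized))^2)
  if (tot == 0) return(0)
  ncol(normalized) * sum((a - mean(a))^2) / tot
}
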