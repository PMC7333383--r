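# Core single-(pseudo-)cell model: cluster-activity posterior modes,
# cross-validated resolution selection, and CRE-activity reconstruction.
#
# Model for a cell j: y_i ~ Poisson(L * mu_sc_i),
# log(mu_sc_i) = h(log mu_i), log(mu_i) = m_i + s_i * delta_i,
# delta = X beta with X the CRE-cluster membership at resolution K,
# beta_k ~ N(0, 1) a priori.

#' Posterior-mode cluster activity
#'
#' Maximizes `sum_{i in C(k)} [y_i h(m_i + s_i b) - L exp(h(m_i + s_i b))]
#' - b^2/2` over the shared activity b of one CRE cluster. The N(0,1) prior
#' regularizes sparse clusters; when every `s_i` is 0 the likelihood does not
#' depend on b and the prior mode 0 is returned. Solved by a coarse grid
#' bracket followed by Brent's method on `[-bound, bound]`.
#'
#' @param y counts of the cluster's CREs in the (pseudo-)cell.
#' @param m,s locus effects of the cluster's CREs.
#' @param spline a `bias_spline` (or NULL for the identity map).
#' @param L library factor.
#' @param bound search bound (default 10; the prior makes larger modes
#'   effectively impossible).
#' @return the scalar posterior mode `beta`.
#' @export
estimate_cluster_activity <- function(y, m, s, spline = NULL, L = 1,
                                      bound = 10) {
  keep <- is.finite(m) & s > 0
  if (!any(keep)) return(0)
  y <- y[keep]; m <- m[keep]; s <- s[keep]
  h <- if (is.null(spline)) identity else function(x) evaluate_bias(spline, x)
  obj <- function(b) {
    eta <- h(m + s * b)
    sum(y * eta - L * exp(eta)) - b^2 / 2
  }
  grid <- seq(-bound, bound, by = 0.25)
  vals <- vapply(grid, obj, 0)
  b0 <- grid[which.max(vals)]
  opt <- optimize(obj, lower = max(-bound, b0 - 0.3),
                  upper = min(bound, b0 + 0.3), maximum = TRUE,
                  tol = 1e-9)
  opt$maximum
}

beta_per_cluster <- function(y, m, s, labels, spline, L, bound = 10) {
  ks <- sort(unique(labels))
  beta <- setNames(numeric(length(ks)), ks)
  for (k in ks) {
    idx <- which(labels == k)
    beta[as.character(k)] <-
      estimate_cluster_activity(y[idx], m[idx], s[idx], spline, L, bound)
  }
  beta
}

#' Choose the resolution K by cross-validation
#'
#' CREs are split once into 90% training / 10% test (seeded). For each
#' candidate level, cluster activities are estimated from the training CREs
#' (clusters without training CREs get the prior mode 0), and each test CRE's
#' exact Poisson log-likelihood under the model is computed with its
#' cluster's activity. The level with the largest median test log-likelihood
#' wins; ties go to the smaller K (coarser, better regularized).
#'
#' @param y counts of the (pseudo-)cell at the catalog CREs.
#' @param hierarchy a `cre_hierarchy` over the catalog.
#' @param effects data.frame with `m`, `s` for the catalog CREs.
#' @param spline a `bias_spline` (or NULL for identity).
#' @param L library factor.
#' @param candidates levels to consider (default: all hierarchy levels).
#' @param train_frac training fraction (default 0.9).
#' @param seed RNG seed for the split.
#' @param repeats number of random splits averaged (default 1).
#' @param test_ids optional explicit test-set indices (overrides the random
#'   split; used e.g. to check order-invariance properties).
#' @return list with `chosen_K`, `scores` (median test log-likelihood per
#'   level) and `level_col` (column index into the hierarchy).
#' @export
cross_validate_K <- function(y, hierarchy, effects, spline, L,
                             candidates = NULL, train_frac = 0.9, seed = 1,
                             repeats = 1, test_ids = NULL) {
  n <- nrow(hierarchy$assignment)
  if (n < 10) stop("insufficient CREs for CV")
  stopifnot(length(y) == n, nrow(effects) == n)
  candidates <- candidates %||% hierarchy$levels
  cols <- match(candidates, hierarchy$levels)
  if (anyNA(cols)) stop("candidate level absent from hierarchy")
  h <- if (is.null(spline)) identity else function(x) evaluate_bias(spline, x)
  scores <- matrix(NA_real_, repeats, length(cols))
  set.seed(seed)
  for (r in seq_len(repeats)) {
    test <- test_ids %||% sample(n, max(1, round((1 - train_frac) * n)))
    train <- setdiff(seq_len(n), test)
    for (ci in seq_along(cols)) {
      lab <- hierarchy$assignment[, cols[ci]]
      beta <- beta_per_cluster(y[train], effects$m[train], effects$s[train],
                               lab[train], spline, L)
      b_test <- beta[as.character(lab[test])]
      b_test[is.na(b_test)] <- 0          # empty training cluster
      eta <- h(effects$m[test] + effects$s[test] * b_test)
      ll <- dpois(y[test], L * exp(eta), log = TRUE)
      scores[r, ci] <- median(ll)
    }
  }
  sc <- colMeans(scores)
  best <- which(sc == max(sc))[1]         # ties -> smaller K (sorted asc)
  list(chosen_K = candidates[best], scores = setNames(sc, candidates),
       level_col = cols[best])
}

#' Reconstruct CRE activities of a (pseudo-)cell
#'
#' Estimates each cluster's activity by posterior mode on all catalog CREs,
#' sets `delta = X beta`, and returns `mu = exp(m + s * delta)` (bulk scale)
#' and `mu_sc = exp(h(log mu))` (single-cell scale).
#'
#' @param y counts at the catalog CREs.
#' @param labels cluster membership of each CRE at the chosen level.
#' @param effects data.frame with `m`, `s` for the catalog CREs.
#' @param spline a `bias_spline` (or NULL for identity).
#' @param L library factor.
#' @param K resolution label stored in the result (default:
#'   `length(unique(labels))`).
#' @return A `reconstructed_signal`: list with `mu`, `mu_sc`, `delta`,
#'   `beta`, `labels`, `chosen_K`.
#' @export
reconstruct <- function(y, labels, effects, spline = NULL, L = 1, K = NULL) {
  stopifnot(length(y) == length(labels), nrow(effects) == length(y))
  beta <- beta_per_cluster(y, effects$m, effects$s, labels, spline, L)
  delta <- unname(beta[as.character(labels)])
  logmu <- effects$m + effects$s * delta
  h <- if (is.null(spline)) identity else function(x) evaluate_bias(spline, x)
  structure(list(mu = exp(logmu), mu_sc = exp(h(logmu)), delta = delta,
                 beta = beta, labels = labels,
                 chosen_K = K %||% length(unique(labels))),
            class = "reconstructed_signal")
}

#' Fit the single-(pseudo-)cell model end to end
#'
#' Fits the technical-bias spline at the low-variability CREs, selects the
#' resolution K by cross-validation, and reconstructs catalog CRE
#' activities.
#'
#' @param cell_counts counts over all genome bins for one (pseudo-)cell.
#' @param compendium a `regulome_compendium` from [build_compendium()].
#' @param L library factor (default: total counts / 1e8).
#' @param candidates candidate K levels (default: all hierarchy levels).
#' @param seed RNG seed (CV split).
#' @return list with `spline`, `cv`, `recon` (a `reconstructed_signal`).
#' @export
reconstruct_cell <- function(cell_counts, compendium, L = NULL,
                           candidates = NULL, seed = 1) {
  L <- L %||% (sum(cell_counts) / 1e8)
  cat_ids <- compendium$catalog$bin_ids
  lv <- compendium$lowvar
  spline <- fit_bias_function(cell_counts[cat_ids[lv$cre]],
                              compendium$effects$m[lv$cre], L)
  y <- cell_counts[cat_ids]
  cv <- cross_validate_K(y, compendium$hierarchy, compendium$effects,
                         spline, L, candidates = candidates, seed = seed)
  lab <- compendium$hierarchy$assignment[, cv$level_col]
  recon <- reconstruct(y, lab, compendium$effects, spline, L,
                       K = cv$chosen_K)
  list(spline = spline, cv = cv, recon = recon)
}

#' Learn all compendium artifacts from bulk counts
#'
#' Runs normalization, signal-bin detection, CRE compilation, genome-wide
#' locus-effect estimation, low-variability selection and multi-resolution
#' CRE clustering in one pass.
#'
#' @param bcm a `bin_count_matrix` of bulk compendium samples.
#' @param species_factor signal-bin background fold cutoff (5 human,
#'   3 mouse).
#' @param stage1_k stage-1 CRE cluster count (default 5000, capped at the
#'   catalog size).
#' @param n_strata,per_stratum low-variability selection parameters.
#' @param seed RNG seed (K-means).
#' @return A `regulome_compendium`: list with `index`, `normalized`, `catalog`,
#'   `effects_genome` (all bins), `effects` (catalog rows), `lowvar`,
#'   `hierarchy`.
#' @export
build_compendium <- function(bcm, species_factor = 5, stage1_k = 5000,
                             n_strata = 10, per_stratum = 1000, seed = 1) {
  norm <- normalize_counts(bcm)
  sig <- detect_signal_bins(bcm, norm, species_factor = species_factor)
  catalog <- compile_cres(sig)
  if (length(catalog$bin_ids) == 0) stop("no CREs detected in compendium")
  eff_all <- estimate_locus_effects(bcm$counts, bcm$library_factors)
  eff <- eff_all[catalog$bin_ids, , drop = FALSE]
  rownames(eff) <- NULL
  lowvar <- select_low_variability(eff, n_strata = min(n_strata,
                                                       nrow(eff)),
                                   per_stratum = per_stratum)
  hier <- cluster_cres(norm[catalog$bin_ids, , drop = FALSE],
                       stage1_k = stage1_k, seed = seed)
  structure(list(index = bcm$index, normalized = norm, catalog = catalog,
                 effects_genome = eff_all, effects = eff, lowvar = lowvar,
                 hierarchy = hier),
            class = "regulome_compendium")
}
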