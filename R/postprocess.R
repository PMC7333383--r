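# Extend reconstructed catalog-CRE activities to the rest of the genome.
# Bins with zero single-cell count stay at zero; other non-catalog bins get
# a boosted-tree prediction trained on the catalog bins with predictors
# (y/L, m, s) and response mu.

#' Predict activity of non-catalog bins and assemble the genome track
#'
#' Unmasked bins fall into three sources: `"cre"` (catalog bins, carrying
#' the reconstructed `mu` unchanged), `"zero"` (bins with zero count in the
#' pseudo-cell, set to 0), and `"predicted"` (remaining bins, regressed from
#' the catalog fit and clipped at 0). Bins with a non-finite compendium
#' baseline `m` are floored to the smallest finite `m` before prediction.
#'
#' @param pseudo_counts per-bin counts of the (pseudo-)cell, all bins.
#' @param L library factor.
#' @param effects_genome locus effects for every bin
#'   (from [estimate_locus_effects()] on the full compendium matrix).
#' @param reconstructed a `reconstructed_signal` over the catalog bins.
#' @param catalog_bin_ids genome-bin row ids of the catalog.
#' @param index the `genome_bin_index`.
#' @param seed accepted for interface symmetry; the boosted fit is
#'   deterministic.
#' @param log_scale if TRUE, regress `log(mu)` instead of `mu`.
#' @param ... passed to [gbt_fit()].
#' @return A `genome_track`: list with `value` (per bin; NA on masked bins),
#'   `source` (`"cre"`/`"predicted"`/`"zero"`/`"masked"`), `index`.
#' @export
predict_noncre_bins <- function(pseudo_counts, L, effects_genome,
                                reconstructed, catalog_bin_ids, index,
                                seed = 1, log_scale = FALSE, ...) {
  n <- index$n_bins
  stopifnot(length(pseudo_counts) == n, nrow(effects_genome) == n)
  if (length(catalog_bin_ids) == 0) stop("no catalog bins to train on")
  value <- numeric(n)
  source <- rep("zero", n)
  source[catalog_bin_ids] <- "cre"
  value[catalog_bin_ids] <- reconstructed$mu
  m <- effects_genome$m
  m[!is.finite(m)] <- min(m[is.finite(m)])
  s <- effects_genome$s
  feats <- cbind(yL = pseudo_counts / L, m = m, s = s)
  resp <- if (log_scale) log(reconstructed$mu) else reconstructed$mu
  if (length(unique(resp)) == 1) {
    warning("constant response; constant prediction")
    model <- NULL
  } else {
    model <- gbt_fit(feats[catalog_bin_ids, , drop = FALSE], resp, ...)
  }
  target <- setdiff(which(pseudo_counts > 0 & !index$masked),
                    catalog_bin_ids)
  if (length(target)) {
    p <- if (is.null(model)) rep(resp[1], length(target)) else
      gbt_predict(model, feats[target, , drop = FALSE])
    if (log_scale) p <- exp(p)
    value[target] <- pmax(p, 0)
    source[target] <- "predicted"
  }
  value[index$masked] <- NA_real_
  source[index$masked] <- "masked"
  structure(list(value = value, source = source, index = index,
                 model = model),
            class = "genome_track")
}

#' Merge catalog reconstructions with non-catalog predictions
#'
#' Catalog values always take precedence; the other sources are disjoint by
#' construction.
#'
#' @param reconstructed a `reconstructed_signal` over the catalog bins.
#' @param predictions a `genome_track` (e.g. from [predict_noncre_bins()]).
#' @param catalog_bin_ids genome-bin row ids of the catalog.
#' @return the merged `genome_track`.
#' @export
assemble_track <- function(reconstructed, predictions, catalog_bin_ids) {
  track <- predictions
  track$value[catalog_bin_ids] <- reconstructed$mu
  track$source[catalog_bin_ids] <- "cre"
  track$value[track$index$masked] <- NA_real_
  track$source[track$index$masked] <- "masked"
  track
}
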