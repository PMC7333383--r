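# Moving-average empirical-FDR peak calling on reconstructed tracks, the
# sensitivity-FDR evaluation curve, and TFBS ranking.

moving_average <- function(value, chrom, W) {
  out <- numeric(length(value))
  for (ch in unique(chrom)) {
    rows <- which(chrom == ch)
    v <- value[rows]; n <- length(v)
    lo <- pmax(seq_len(n) - W, 1L); hi <- pmin(seq_len(n) + W, n)
    cs <- cumsum(c(0, v))
    out[rows] <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
  out
}

#' Total genomic span of the default peak window
#'
#' The moving average at window half-width `W` covers `2W + 1` bins, i.e.
#' `(2W + 1) * bin_width` bp (600 bp at the defaults W = 1, 200-bp bins).
#'
#' @param W window half-width in bins.
#' @param bin_width bin width in bp.
#' @return span in bp.
#' @export
peak_window_span <- function(W = 1, bin_width = 200) {
  (2 * W + 1) * bin_width
}

#' Call peaks by moving-average empirical FDR
#'
#' Each unmasked bin gets the average signal of itself and its `2W`
#' neighbors (windows truncated at chromosome ends). A background
#' distribution is built from `n_background` means of `2W + 1` unmasked bins
#' drawn uniformly at random with replacement (not necessarily neighboring).
#' For moving-average signal s, `FDR(s) = P(background > s) / P(signal >=
#' s)`, monotonized from high to low s; bins with FDR below `fdr_cutoff` are
#' merged into maximal runs of consecutive bins. Peaks are ranked by (FDR
#' ascending, mean signal descending). An all-constant track yields no peaks.
#'
#' @param track a `genome_track`, or a numeric per-bin vector with `index`.
#' @param index required if `track` is a plain vector.
#' @param W window half-width in bins (default 1).
#' @param fdr_cutoff significance cutoff (default 0.05).
#' @param n_background background sample count (default 1e5).
#' @param seed RNG seed for background sampling.
#' @return A `region_set` of peaks with columns `score` (mean moving-average
#'   signal) and `fdr`, ordered by rank; per-bin moving averages and FDRs
#'   are attached as attributes.
#' @export
call_peaks <- function(track, index = NULL, W = 1, fdr_cutoff = 0.05,
                       n_background = 1e5, seed = 1) {
  if (inherits(track, "genome_track")) {
    index <- track$index
    value <- track$value
  } else value <- track
  stopifnot(length(value) == index$n_bins)
  un <- which(!index$masked)
  if (length(un) < 2 * W + 1) stop("track too short for the window")
  v <- value[un]
  v[is.na(v)] <- 0
  chrom <- index$bins$chrom[un]
  ma <- moving_average(v, chrom, W)
  if (diff(range(v)) == 0) {
    warning("all-constant track; no peaks called")
    return(region_set())
  }
  set.seed(seed)
  bg <- rowMeans(matrix(v[sample.int(length(v), n_background * (2 * W + 1),
                                     replace = TRUE)],
                        nrow = n_background))
  o <- order(ma, decreasing = TRUE)
  sorted <- ma[o]
  num <- findInterval(-sorted, sort(-bg), left.open = TRUE) / n_background
  den <- findInterval(-sorted, sort(-sorted)) / length(sorted)  # P(ma >= s)
  fdr_sorted <- cummax(pmin(num / den, 1))               # monotone in rank
  fdr <- numeric(length(ma)); fdr[o] <- fdr_sorted
  # a bin whose window carries no signal is never significant
  sig <- fdr < fdr_cutoff & ma > 0
  if (!any(sig)) return(region_set())
  # merge maximal runs of genomically consecutive significant bins
  gid <- un[sig]
  runs <- cumsum(c(TRUE, diff(gid) != 1L |
                     index$bins$chrom[gid[-1]] !=
                       index$bins$chrom[gid[-length(gid)]]))
  peak_rows <- split(seq_along(gid), runs)
  peaks <- do.call(rbind, lapply(peak_rows, function(rows) {
    b <- gid[rows]
    data.frame(chrom = index$bins$chrom[b[1]],
               start = index$bins$start[b[1]],
               end = index$bins$end[b[length(b)]],
               score = mean(ma[sig][rows]),
               fdr = min(fdr[sig][rows]))
  }))
  o2 <- order(peaks$fdr, -peaks$score)
  peaks <- peaks[o2, , drop = FALSE]
  out <- data.frame(peaks, rank = seq_len(nrow(peaks)))
  rownames(out) <- NULL
  class(out) <- c("region_set", "data.frame")
  attr(out, "moving_average") <- ma
  attr(out, "bin_fdr") <- fdr
  attr(out, "bin_ids") <- un
  out
}

#' Write peaks as BED6+ (name = rank, score = -log10 FDR capped at 1000)
#' @param peaks peak `region_set` from [call_peaks()].
#' @param path output file.
#' @export
write_peaks_bed <- function(peaks, path) {
  if (nrow(peaks) == 0) { writeLines(character(), path); return(invisible(path)) }
  sc <- pmin(-log10(pmax(peaks$fdr, 1e-1000)), 1000)
  lines <- sprintf("%s\t%d\t%d\tpeak_%d\t%.4f\t.\t%.6g\t%.6g",
                   peaks$chrom, peaks$start, peaks$end, peaks$rank, sc,
                   peaks$score, peaks$fdr)
  writeLines(lines, path)
  invisible(path)
}

#' Sensitivity-FDR curve and its area
#'
#' Walks down a ranked prediction list; after each prefix, sensitivity is
#' the fraction of truth regions overlapped (>= 1 bp) by any prediction so
#' far and FDR is the fraction of predictions so far that overlap no truth
#' region. The area is the trapezoidal integral of the monotone envelope of
#' the curve over FDR in [0, 1], with the final sensitivity extended to
#' FDR = 1.
#'
#' @param predictions a ranked `region_set` (rank order = row order, or by
#'   `rank` column if present).
#' @param truth a `region_set` of gold-standard regions.
#' @return list with `curve` (data.frame fdr/sensitivity per prefix) and
#'   `auc`.
#' @export
sensitivity_fdr_curve <- function(predictions, truth) {
  stopifnot(nrow(truth) > 0)
  if (nrow(predictions) == 0)
    return(list(curve = data.frame(fdr = numeric(), sensitivity = numeric()),
                auc = 0))
  if (!is.null(predictions$rank))
    predictions <- predictions[order(predictions$rank), , drop = FALSE]
  hits <- GenomicRanges::findOverlaps(as_granges_raw(predictions),
                                      as_granges_raw(truth),
                                      minoverlap = 1L)
  qh <- S4Vectors::queryHits(hits); th <- S4Vectors::subjectHits(hits)
  n_pred <- nrow(predictions); n_truth <- nrow(truth)
  first_hit <- rep(NA_integer_, n_truth)   # earliest prefix covering truth t
  if (length(qh)) {
    agg <- tapply(qh, th, min)
    first_hit[as.integer(names(agg))] <- as.integer(agg)
  }
  is_tp <- seq_len(n_pred) %in% qh
  cum_fp <- cumsum(!is_tp)
  sens <- cumsum(tabulate(first_hit[!is.na(first_hit)], n_pred)) / n_truth
  fdr <- cum_fp / seq_len(n_pred)
  curve <- data.frame(fdr = fdr, sensitivity = sens)
  # monotone envelope (best sensitivity at FDR <= f), extended to FDR = 1
  env_f <- c(cummax(fdr), 1)
  env_s <- c(cummax(sens), max(sens))
  keep <- !duplicated(env_f, fromLast = TRUE)
  f <- env_f[keep]; s <- env_s[keep]
  f2 <- c(0, f)
  s2 <- c(if (f[1] == 0) s[1] else 0, s)
  auc <- sum(diff(f2) * (s2[-length(s2)] + s2[-1]) / 2)
  list(curve = curve, auc = auc)
}

as_granges_raw <- function(rs) {
  GenomicRanges::GRanges(rs$chrom,
                         IRanges::IRanges(start = rs$start + 1L,
                                          end = rs$end))
}

#' Rank motif-site bins by reconstructed signal
#'
#' Motif-containing bins are ranked by the track signal overlapping them
#' (descending; ties broken by genome order), predicting TF binding sites.
#'
#' @param track a `genome_track` or per-bin numeric vector.
#' @param motif_bins a `region_set` of motif-containing bins.
#' @param index required if `track` is a plain vector.
#' @return the motif bins as a `region_set` with `score` (signal) and
#'   `rank`, ordered by rank.
#' @export
predict_tfbs <- function(track, motif_bins, index = NULL) {
  if (inherits(track, "genome_track")) {
    index <- track$index
    value <- track$value
  } else value <- track
  value[is.na(value)] <- 0
  hits <- GenomicRanges::findOverlaps(as_granges_raw(motif_bins),
                                      as_granges_raw(index$bins))
  sig <- rep(0, nrow(motif_bins))
  if (length(hits)) {
    agg <- tapply(value[S4Vectors::subjectHits(hits)],
                  S4Vectors::queryHits(hits), mean)
    sig[as.integer(names(agg))] <- agg
  }
  o <- order(-sig, motif_bins$chrom, motif_bins$start)
  out <- motif_bins[o, c("chrom", "start", "end"), drop = FALSE]
  out$score <- sig[o]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("region_set", "data.frame")
  out
}
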