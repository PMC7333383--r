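#' @importFrom stats quantile median rnorm runif rpois dpois optim optimize
#'   prcomp kmeans hclust cutree dist lm predict coef sd cor setNames
#' @importFrom utils read.table write.table head capture.output
#' @importFrom methods as
NULL

# ---------------------------------------------------------------------------
# RegionSet: sorted half-open genomic intervals (0-based, BED convention)
# ---------------------------------------------------------------------------

#' Create a region set
#'
#' A `region_set` is a sorted table of half-open, 0-based genomic intervals
#' (BED convention), optionally carrying a numeric score and a rank. It is the
#' carrier type for blacklists, CRE catalogs, peaks and motif-site bins.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors; intervals are `[start, end)` with
#'   `start < end`.
#' @param score optional numeric score per interval.
#' @param rank optional integer rank per interval (kept as given, not sorted).
#' @return A `region_set` data.frame sorted by `(chrom, start)`.
#' @export
region_set <- function(chrom = character(), start = integer(),
                       end = integer(), score = NULL, rank = NULL) {
  stopifnot(length(chrom) == length(start), length(start) == length(end))
  if (length(start) && any(start >= end))
    stop("region_set: all intervals must satisfy start < end")
  df <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                   end = as.integer(end), stringsAsFactors = FALSE)
  if (!is.null(score)) df$score <- as.numeric(score)
  if (!is.null(rank)) df$rank <- as.integer(rank)
  o <- order(df$chrom, df$start, df$end)
  df <- df[o, , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("region_set", "data.frame")
  df
}

as_granges <- function(rs) {
  GenomicRanges::GRanges(rs$chrom,
                         IRanges::IRanges(start = rs$start + 1L, end = rs$end))
}

# ---------------------------------------------------------------------------
# GenomeBinIndex
# ---------------------------------------------------------------------------

#' Segment a genome into fixed-width bins
#'
#' Divides each chromosome into non-overlapping `bin_width`-bp bins (default
#' 200 bp, the resolution at which CRE activity is modeled). A trailing
#' partial bin is kept and flagged. Bins overlapping the exclusion
#' ("blacklist") regions by at least 1 bp are masked: their counts are kept
#' internally (so library factors reflect sequencing depth) but they are
#' excluded from CRE compilation, background sampling and peak output.
#'
#' @param chrom_sizes named integer vector of chromosome lengths in bp.
#' @param bin_width bin width in bp (default 200).
#' @param blacklist optional `region_set` of regions to mask; intervals are
#'   clipped to chromosome bounds.
#' @return A `genome_bin_index` with elements `chrom_sizes`, `bin_width`,
#'   `bins` (data.frame chrom/start/end), `masked` and `partial` logical
#'   vectors, and `n_bins`.
#' @export
segment_genome <- function(chrom_sizes, bin_width = 200L, blacklist = NULL) {
  if (length(chrom_sizes) == 0) stop("no genome")
  stopifnot(bin_width > 0, all(chrom_sizes > 0), !is.null(names(chrom_sizes)))
  bin_width <- as.integer(bin_width)
  per <- lapply(names(chrom_sizes), function(ch) {
    len <- as.integer(chrom_sizes[[ch]])
    starts <- seq.int(0L, len - 1L, by = bin_width)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + bin_width, len),
               stringsAsFactors = FALSE)
  })
  bins <- do.call(rbind, per)
  partial <- (bins$end - bins$start) < bin_width
  masked <- rep(FALSE, nrow(bins))
  if (!is.null(blacklist) && nrow(blacklist) > 0) {
    bl <- blacklist
    keep <- bl$chrom %in% names(chrom_sizes)
    bl <- bl[keep, , drop = FALSE]
    if (nrow(bl)) {
      bl$end <- pmin(bl$end, as.integer(chrom_sizes[bl$chrom]))
      bl$start <- pmax(bl$start, 0L)
      bl <- bl[bl$start < bl$end, , drop = FALSE]
    }
    if (nrow(bl)) {
      hits <- GenomicRanges::findOverlaps(
        as_granges(bins), as_granges(bl), minoverlap = 1L)
      masked[unique(S4Vectors::queryHits(hits))] <- TRUE
    }
  }
  structure(list(chrom_sizes = chrom_sizes, bin_width = bin_width,
                 bins = bins, masked = masked, partial = partial,
                 n_bins = nrow(bins)),
            class = "genome_bin_index")
}

#' @export
print.genome_bin_index <- function(x, ...) {
  cat(sprintf("genome_bin_index: %d bins of %d bp on %d chromosome(s); %d masked\n",
              x$n_bins, x$bin_width, length(x$chrom_sizes), sum(x$masked)))
  invisible(x)
}

# map genomic positions to bin row indices (NA if off-genome)
bin_of_position <- function(index, chrom, pos) {
  first <- c(1L, 1L + cumsum(tabulate(
    match(index$bins$chrom, names(index$chrom_sizes)),
    nbins = length(index$chrom_sizes))))
  ci <- match(chrom, names(index$chrom_sizes))
  len <- unname(index$chrom_sizes[ci])
  ok <- !is.na(ci) & pos >= 0 & pos < len
  out <- rep(NA_integer_, length(pos))
  out[ok] <- first[ci[ok]] + pos[ok] %/% index$bin_width
  out
}

# ---------------------------------------------------------------------------
# BinCountMatrix
# ---------------------------------------------------------------------------

#' Construct a bin-count matrix
#'
#' @param counts nonnegative integer matrix, bins x samples.
#' @param index a `genome_bin_index` with `nrow(counts)` bins.
#' @param sample_ids sample labels; default column names or S1..Sn.
#' @param library_factors per-sample library factor `L_j`; defaults to
#'   column total / 1e8 (library size in units of a hundred million reads).
#' @return A `bin_count_matrix`.
#' @export
bin_count_matrix <- function(counts, index, sample_ids = NULL,
                             library_factors = NULL) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == index$n_bins, all(counts >= 0),
            all(counts == round(counts)))
  if (is.null(sample_ids))
    sample_ids <- colnames(counts) %||% paste0("S", seq_len(ncol(counts)))
  if (is.null(library_factors)) library_factors <- colSums(counts) / 1e8
  stopifnot(length(library_factors) == ncol(counts))
  dimnames(counts) <- list(NULL, sample_ids)
  structure(list(counts = counts, index = index, sample_ids = sample_ids,
                 library_factors = as.numeric(library_factors)),
            class = "bin_count_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Count read 5' positions into genome bins
#'
#' Each read is assigned to exactly one bin by its 5' start coordinate
#' (0-based). Reads on chromosomes absent from the index, or beyond
#' chromosome bounds, are tallied as skipped and reported via a message.
#' Library factors include reads falling in masked bins.
#'
#' @param reads a list (one element per sample) of data.frames with columns
#'   `chrom` and `start` (a `region_set` works; only the start is used).
#' @param index a `genome_bin_index`.
#' @param sample_ids optional sample labels (default: names of `reads`).
#' @return A `bin_count_matrix`; the number of skipped reads per sample is
#'   attached as attribute `"skipped"`.
#' @export
count_reads_in_bins <- function(reads, index, sample_ids = NULL) {
  stopifnot(is.list(reads))
  if (is.data.frame(reads)) reads <- list(reads)
  n <- index$n_bins
  counts <- matrix(0L, n, length(reads))
  skipped <- integer(length(reads))
  for (j in seq_along(reads)) {
    r <- reads[[j]]
    if (nrow(r) == 0) next
    b <- bin_of_position(index, r$chrom, r$start)
    skipped[j] <- sum(is.na(b))
    b <- b[!is.na(b)]
    if (length(b)) counts[, j] <- tabulate(b, nbins = n)
  }
  if (any(skipped > 0))
    message("count_reads_in_bins: skipped ", sum(skipped),
            " off-genome read(s)")
  ids <- sample_ids %||% names(reads) %||% paste0("S", seq_along(reads))
  out <- bin_count_matrix(counts, index, sample_ids = ids)
  if (any(out$library_factors == 0))
    message("count_reads_in_bins: sample(s) with zero reads: ",
            paste(ids[out$library_factors == 0], collapse = ", "))
  attr(out, "skipped") <- skipped
  out
}
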