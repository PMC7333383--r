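# Readers/writers for the plain-text formats the pipeline exchanges:
# BED (regions), bedGraph (signal tracks), MatrixMarket MTX / TSV (counts).
# All coordinates are 0-based half-open.

#' Write / read a region set as BED
#'
#' Intervals are sorted on write. An optional `score` column is written as the
#' 5th BED field (4th field is a running name), formatted to 6 significant
#' digits.
#'
#' @param regions a `region_set`.
#' @param path output file.
#' @export
write_regions_bed <- function(regions, path) {
  rs <- region_set(regions$chrom, regions$start, regions$end,
                   score = regions$score)
  if (!is.null(rs$score)) {
    lines <- sprintf("%s\t%d\t%d\tregion_%d\t%s", rs$chrom, rs$start, rs$end,
                     seq_len(nrow(rs)), formatC(rs$score, digits = 6,
                                                format = "g"))
  } else if (nrow(rs)) {
    lines <- sprintf("%s\t%d\t%d", rs$chrom, rs$start, rs$end)
  } else lines <- character()
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_regions_bed
#' @export
read_regions_bed <- function(path) {
  if (file.size(path) == 0)
    return(region_set())
  df <- read.table(path, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE)
  region_set(df[[1]], df[[2]], df[[3]],
             score = if (ncol(df) >= 5) as.numeric(df[[5]]) else NULL)
}

#' Write / read a per-bin signal track as bedGraph
#'
#' One line per unmasked bin with a nonzero value; values are printed with
#' full (17 significant digit) precision so that write-then-read round-trips
#' bit-exactly.
#'
#' @param signal numeric vector, one value per bin of `index`.
#' @param index a `genome_bin_index`.
#' @param path output file.
#' @export
write_signal_track <- function(signal, index, path) {
  if (length(signal) != index$n_bins)
    stop("signal length does not match bin index")
  keep <- !index$masked & signal != 0 & !is.na(signal)
  b <- index$bins[keep, , drop = FALSE]
  lines <- sprintf("%s\t%d\t%d\t%s", b$chrom, b$start, b$end,
                   sprintf("%.17g", signal[keep]))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_signal_track
#' @return `read_signal_track` returns a numeric vector over all bins of
#'   `index` (zero where absent from the file).
#' @export
read_signal_track <- function(path, index) {
  out <- numeric(index$n_bins)
  if (file.size(path) == 0) return(out)
  df <- read.table(path, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE)
  b <- bin_of_position(index, df[[1]], df[[2]])
  if (any(is.na(b))) stop("bedGraph line outside the bin index")
  out[b] <- df[[4]]
  out
}

#' Write / read a bin-count matrix
#'
#' Writes a MatrixMarket `.mtx` (or dense `.tsv`) alongside a bin BED (score
#' column = 1 for masked bins) and a sample table with library factors.
#'
#' @param bcm a `bin_count_matrix`.
#' @param prefix path prefix; files `<prefix>.mtx` (or `.tsv`),
#'   `<prefix>.bins.bed`, `<prefix>.samples.tsv` are written.
#' @param format `"mtx"` (sparse) or `"tsv"` (dense).
#' @export
write_count_matrix <- function(bcm, prefix, format = c("mtx", "tsv")) {
  format <- match.arg(format)
  mat_path <- paste0(prefix, ".", format)
  if (format == "mtx") {
    Matrix::writeMM(methods::as(Matrix::Matrix(bcm$counts, sparse = TRUE),
                                "generalMatrix"), mat_path)
  } else {
    write.table(bcm$counts, mat_path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = TRUE)
  }
  idx <- bcm$index
  writeLines(sprintf("%s\t%d\t%d\tbin_%d\t%d", idx$bins$chrom, idx$bins$start,
                     idx$bins$end, seq_len(idx$n_bins),
                     as.integer(idx$masked)),
             paste0(prefix, ".bins.bed"))
  smp <- data.frame(sample_id = bcm$sample_ids,
                    library_factor = sprintf("%.17g", bcm$library_factors))
  write.table(smp, paste0(prefix, ".samples.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(prefix)
}

#' @rdname write_count_matrix
#' @param path count matrix file (`.mtx` or `.tsv`).
#' @param bin_bed bin BED as written by `write_count_matrix`.
#' @param sample_tsv sample table as written by `write_count_matrix`.
#' @export
read_count_matrix <- function(path, bin_bed, sample_tsv = NULL) {
  bins <- read.table(bin_bed, sep = "\t", header = FALSE,
                     stringsAsFactors = FALSE)
  chrom_sizes <- tapply(bins[[3]], bins[[1]], max)
  widths <- bins[[3]] - bins[[2]]
  bw <- as.integer(max(widths))
  index <- segment_genome(chrom_sizes[unique(bins[[1]])], bw)
  if (index$n_bins != nrow(bins)) stop("malformed bin BED")
  index$masked <- if (ncol(bins) >= 5) bins[[5]] != 0 else
    rep(FALSE, nrow(bins))
  if (grepl("\\.mtx$", path)) {
    counts <- as.matrix(Matrix::readMM(path))
  } else {
    counts <- as.matrix(read.table(path, sep = "\t", header = TRUE,
                                   check.names = FALSE))
    if (!is.numeric(counts)) stop("malformed count TSV")
  }
  if (nrow(counts) != index$n_bins) stop("count matrix / bin BED mismatch")
  ids <- NULL; L <- NULL
  if (!is.null(sample_tsv)) {
    smp <- read.table(sample_tsv, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE)
    ids <- smp$sample_id
    L <- as.numeric(smp$library_factor)
  }
  bin_count_matrix(counts, index, sample_ids = ids, library_factors = L)
}

#' Write locus effects to TSV
#'
#' Columns: chrom, start, end, m, s, fallback (per catalog/genome bin).
#' @param effects data.frame from [estimate_locus_effects()].
#' @param index the matching `genome_bin_index`.
#' @param path output file.
#' @export
write_locus_effects <- function(effects, index, path) {
  stopifnot(nrow(effects) == index$n_bins)
  out <- data.frame(index$bins, m = sprintf("%.10g", effects$m),
                    s = sprintf("%.10g", effects$s),
                    fallback = as.integer(effects$fallback))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a CRE hierarchy to TSV (one column per level, header `K=<value>`)
#' @param hierarchy a `cre_hierarchy`.
#' @param path output file.
#' @export
write_hierarchy <- function(hierarchy, path) {
  m <- hierarchy$assignment
  colnames(m) <- paste0("K=", hierarchy$levels)
  write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
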