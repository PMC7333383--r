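# Shared fixture builders. Everything is generated in code; no binary data.

# a toy single-chromosome index
toy_index <- function(n_bins = 10, bin_width = 200, chrom = "chr1",
                      blacklist = NULL) {
  segment_genome(setNames(n_bins * bin_width, chrom), bin_width, blacklist)
}

# a bin_count_matrix with given counts on a toy index
toy_bcm <- function(counts, bin_width = 200, library_factors = NULL) {
  counts <- as.matrix(counts)
  idx <- toy_index(nrow(counts), bin_width)
  bin_count_matrix(counts, idx, library_factors = library_factors)
}

# independent brute-force tally of reads into bins (oracle for counting)
brute_tally <- function(reads_df, index) {
  out <- integer(index$n_bins)
  for (r in seq_len(nrow(reads_df))) {
    hit <- which(index$bins$chrom == reads_df$chrom[r] &
                   index$bins$start <= reads_df$start[r] &
                   index$bins$end > reads_df$start[r])
    if (length(hit) == 1) out[hit] <- out[hit] + 1L
  }
  out
}

# dense grid-search oracle for the cluster-activity posterior mode
# (vectorized over the grid so a 1e-4 step on [-6, 6] stays fast)
grid_beta_oracle <- function(y, m, s, L = 1, lo = -6, hi = 6, step = 1e-4) {
  grid <- seq(lo, hi, by = step)
  eta <- sweep(outer(grid, s), 2, m, "+")      # grid x CREs
  obj <- drop(eta %*% y) - L * rowSums(exp(eta)) - grid^2 / 2
  grid[which.max(obj)]
}

# bisection oracle for the root of exp(b) + b = 0 (empty-data stationarity)
bisect_root <- function(f, lo, hi, tol = 1e-10) {
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(lo) * f(mid) <= 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}
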