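# Genome binning, read counting, and the plain-text I/O layer.

test_that("segment_genome partitions the genome and applies the blacklist", {
  idx <- segment_genome(c(chr1 = 1000L), 200L)
  expect_equal(idx$n_bins, 5)
  expect_false(any(idx$masked))
  expect_equal(idx$bins$start, seq(0, 800, 200))

  bl <- region_set("chr1", 350L, 360L)
  idx2 <- segment_genome(c(chr1 = 1000L), 200L, bl)
  expect_equal(which(idx2$masked), 2L)   # bin (200, 400) overlaps

  # clipping convention: 999-bp chromosome keeps a flagged partial last bin
  idx3 <- segment_genome(c(chr1 = 999L), 200L)
  expect_equal(unlist(idx3$bins[5, c("start", "end")], use.names = FALSE),
               c(800L, 999L))
  expect_equal(which(idx3$partial), 5L)

  # partition invariant: every bp in exactly one bin
  idx4 <- segment_genome(c(chrA = 999L, chrB = 450L), 200L)
  expect_equal(sum(idx4$bins$end - idx4$bins$start), 999 + 450)
  expect_true(all(tapply(idx4$bins$start, idx4$bins$chrom,
                         function(s) !anyDuplicated(s))))

  expect_error(segment_genome(integer(0)), "no genome")
})

test_that("count_reads_in_bins assigns by 5' start and conserves reads", {
  idx <- toy_index(3)
  one <- list(A = data.frame(chrom = "chr1", start = 250L))
  bcm <- count_reads_in_bins(one, idx)
  expect_equal(unname(bcm$counts[, 1]), c(0L, 1L, 0L))

  none <- list(A = data.frame(chrom = character(), start = integer()))
  bcm0 <- count_reads_in_bins(none, idx)
  expect_true(all(bcm0$counts == 0))
  expect_equal(bcm0$library_factors, 0)

  set.seed(42)
  reads <- data.frame(chrom = "chr1", start = sample.int(600, 10) - 1L)
  bcm10 <- count_reads_in_bins(list(S = reads), idx)
  expect_equal(unname(bcm10$counts[, 1]), brute_tally(reads, idx))
  expect_equal(sum(bcm10$counts), 10)
  expect_equal(bcm10$library_factors, 10 / 1e8)

  # off-genome reads go to the skipped tally, not a bin
  off <- data.frame(chrom = c("chr1", "chr9", "chr1"),
                    start = c(100L, 5L, 4000L))
  expect_message(bcm_off <- count_reads_in_bins(list(S = off), idx),
                 "skipped 2")
  expect_equal(sum(bcm_off$counts), 1)
})

test_that("bedGraph signal tracks round-trip bit-exactly", {
  idx <- toy_index(6)
  sig <- c(0, 1.25, pi, 0, 1e-7, 123456.789)
  path <- withr::local_tempfile(fileext = ".bedgraph")
  write_signal_track(sig, idx, path)
  expect_identical(read_signal_track(path, idx), sig)

  write_signal_track(numeric(6), idx, path)
  expect_identical(readLines(path), character(0))

  idx3 <- toy_index(3)
  write_signal_track(c(0, 2.5, 1), idx3, path)
  expect_identical(readLines(path),
                   c("chr1\t200\t400\t2.5", "chr1\t400\t600\t1"))

  expect_error(write_signal_track(1:5, idx3), "match")
})

test_that("count matrices round-trip through MTX and TSV and agree", {
  set.seed(7)
  bcm <- toy_bcm(matrix(rpois(40, 3), 10, 4))
  dir <- withr::local_tempdir()
  for (fmt in c("mtx", "tsv")) {
    prefix <- file.path(dir, fmt)
    write_count_matrix(bcm, prefix, format = fmt)
    back <- read_count_matrix(paste0(prefix, ".", fmt),
                              paste0(prefix, ".bins.bed"),
                              paste0(prefix, ".samples.tsv"))
    expect_equal(unname(back$counts), unname(bcm$counts))
    expect_equal(back$library_factors, bcm$library_factors)
    expect_equal(back$index$bins, bcm$index$bins)
  }
  # sparse and dense readers agree with each other
  a <- read_count_matrix(file.path(dir, "mtx.mtx"),
                         file.path(dir, "mtx.bins.bed"))
  b <- read_count_matrix(file.path(dir, "tsv.tsv"),
                         file.path(dir, "tsv.bins.bed"))
  expect_equal(unname(a$counts), unname(b$counts))

  writeLines(c("not\ta\theader", "chr1\tx\ty"), file.path(dir, "bad.tsv"))
  expect_error(read_count_matrix(file.path(dir, "bad.tsv"),
                                 file.path(dir, "mtx.bins.bed")))
})

test_that("region BED I/O sorts, round-trips, and keeps 6 sig. digits", {
  rs <- region_set(c("chr2", "chr1", "chr1"), c(100L, 500L, 0L),
                   c(300L, 700L, 200L), score = c(1.23456789, 2, 0.000123456))
  expect_equal(rs$chrom, c("chr1", "chr1", "chr2"))   # sorted on construction
  path <- withr::local_tempfile(fileext = ".bed")
  write_regions_bed(rs, path)
  back <- read_regions_bed(path)
  expect_equal(back$chrom, rs$chrom)
  expect_equal(back$start, rs$start)
  expect_equal(back$end, rs$end)
  expect_equal(back$score, signif(rs$score, 6))

  write_regions_bed(region_set(), path)
  expect_equal(nrow(read_regions_bed(path)), 0)
})
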