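# Compendium statistics: normalization, signal bins, catalog, locus
# effects, low-variability set, clustering, variance explained.

test_that("normalize_counts computes log2(y/L + 1)", {
  bcm <- toy_bcm(matrix(c(0L, 2L, 300L), 3, 1), library_factors = 2)
  norm <- normalize_counts(bcm)
  expect_equal(unname(norm[, 1]), c(0, 1, log2(151)))
  bcm3 <- toy_bcm(matrix(300L, 1, 1), library_factors = 3)
  expect_equal(unname(normalize_counts(bcm3)[1, 1]), log2(101),
               tolerance = 1e-10)
  bad <- toy_bcm(matrix(5L, 1, 1), library_factors = 0)
  expect_error(normalize_counts(bad), "zero library factor")
})

test_that("signal-bin detection applies the three cutoffs", {
  # y = 9 fails the raw-count rule no matter how extreme the enrichment
  b1 <- toy_bcm(matrix(c(9L, rep(0L, 9)), 10, 1), library_factors = 1e-4)
  expect_false(any(detect_signal_bins(b1)))

  # y = 64, L = 1, empty neighborhood: ytilde ~ 6.02 >= 5, background 0
  b2 <- toy_bcm(matrix(c(rep(0L, 5), 64L, rep(0L, 4)), 10, 1),
                library_factors = 1)
  expect_equal(which(detect_signal_bins(b2)[, 1]), 6L)

  # ytilde = 5.5 against background mean 2 fails 5.5 >= 5 * 2
  y_target <- as.integer(round(2^5.5 - 1))           # ytilde ~ 5.5 at L = 1
  y_bg <- as.integer(round(2^2 - 1))                 # ytilde = 2
  b3 <- toy_bcm(matrix(c(rep(y_bg, 5), y_target, rep(y_bg, 4)), 10, 1),
                library_factors = 1)
  norm3 <- normalize_counts(b3)
  expect_gt(y_target, 10)
  expect_equal(unname(norm3[6, 1]), 5.5, tolerance = 0.05)
  expect_false(detect_signal_bins(b3)[6, 1])
  # a laxer fold cutoff admits the same bin (5.5 >= 2 * 2)
  expect_true(detect_signal_bins(b3, species_factor = 2)[6, 1])

  # masked bins are never flagged
  idx <- toy_index(10, blacklist = region_set("chr1", 1000L, 1200L))
  b4 <- bin_count_matrix(matrix(c(rep(0L, 5), 64L, rep(0L, 4)), 10, 1), idx,
                         library_factors = 1)
  expect_false(any(detect_signal_bins(b4)))

  expect_error(detect_signal_bins(b2, bg_window_bp = 100), "window")
})

test_that("compile_cres is the union over samples; saturation as defined", {
  sig <- cbind(c(TRUE, FALSE, FALSE, FALSE),
               c(TRUE, TRUE, FALSE, FALSE),
               c(FALSE, FALSE, TRUE, FALSE))
  cat <- compile_cres(sig)
  expect_equal(cat$bin_ids, which(apply(sig, 1, any)))   # brute-force union
  expect_equal(dim(cat$support), c(3L, 3L))

  expect_equal(catalog_saturation(1:10, c(3, 7)), 0)
  expect_equal(catalog_saturation(integer(0), 1:4), 1)
  expect_equal(catalog_saturation(1:98, c(5, 99, 100)), 2 / 100)
})

test_that("moment estimator matches hand computations and the fallback", {
  # constant y = 5: ratio = (25 - 5)/25 < 1 forces the degenerate branch
  eff <- estimate_locus_effects(matrix(5L, 1, 6), rep(1, 6))
  expect_equal(eff$s, 0)
  expect_equal(eff$m, log(5))
  expect_true(eff$fallback)

  # y = (1, 3): moments 2, 5, 2; ratio 0.75 < 1
  eff2 <- estimate_locus_effects(matrix(c(1L, 3L), 1, 2), c(1, 1))
  expect_equal(eff2$s, 0)
  expect_equal(eff2$m, log(2))

  # all-zero row: -Inf sentinel
  eff3 <- estimate_locus_effects(matrix(0L, 1, 3), c(1, 2, 1))
  expect_equal(eff3$m, -Inf)
  expect_equal(eff3$s, 0)
})

test_that("moment estimator recovers (m, s) from the generative model", {
  set.seed(11)
  J <- 10000
  y <- matrix(rpois(J, exp(1 + 0.8 * rnorm(J))), 1, J)
  eff <- estimate_locus_effects(y, rep(1, J))
  expect_lt(abs(eff$m - 1), 0.05)
  expect_lt(abs(eff$s - 0.8), 0.05)
})

test_that("moment estimator never yields NaN or negative s (property)", {
  set.seed(5)
  for (rep in 1:20) {
    J <- sample(2:8, 1)
    y <- matrix(rpois(10 * J, 0.5), 10, J)
    y[1, 1] <- 1L          # guarantee one nonzero entry
    L <- runif(J, 0.2, 3)
    eff <- estimate_locus_effects(y, L)
    expect_false(any(is.nan(eff$m)))
    expect_false(any(is.nan(eff$s)))
    expect_true(all(eff$s >= 0))
    nz <- rowSums(y) > 0
    expect_true(all(is.finite(eff$m[nz])))
  }
})

test_that("low-variability selection stratifies by m and takes smallest s", {
  # ample CREs per stratum: exactly n_strata * per_stratum selected
  set.seed(3)
  n <- 400
  eff <- data.frame(m = seq(0, 4, length.out = n), s = runif(n),
                    fallback = FALSE)
  lv <- select_low_variability(eff, n_strata = 10, per_stratum = 20)
  expect_equal(nrow(lv), 200)
  expect_equal(sort(unique(lv$stratum)), 1:10)

  # fewer CREs than the cap: all selected
  eff50 <- data.frame(m = rnorm(50), s = runif(50), fallback = FALSE)
  expect_equal(nrow(select_low_variability(eff50)), 50)

  # stable tie-break: equal s picks the lowest genome indices per stratum
  eff_tie <- data.frame(m = rep(c(0, 10), each = 10), s = rep(1, 20),
                        fallback = FALSE)
  lv_tie <- select_low_variability(eff_tie, n_strata = 2, per_stratum = 3)
  expect_equal(lv_tie$cre, c(1:3, 11:13))

  # brute-force check of the within-stratum rule
  eff_b <- data.frame(m = rep(1, 30), s = rev(seq_len(30)), fallback = FALSE)
  lv_b <- select_low_variability(eff_b, n_strata = 1, per_stratum = 5)
  expect_equal(sort(lv_b$cre), 26:30)
})

test_that("coarse halving levels match the published sequence", {
  expect_equal(coarse_levels(5000), c(5000, 2500, 1250, 625, 312, 156))
})

test_that("cluster_cres recovers planted blocks and nests its levels", {
  set.seed(21)
  blocks <- rep(1:4, each = 5)
  base <- matrix(rnorm(4 * 12, sd = 3), 4, 12)
  x <- base[blocks, ] + matrix(rnorm(20 * 12, sd = 0.01), 20, 12)
  h <- cluster_cres(x, stage1_k = 4, seed = 7)
  expect_equal(adjusted_rand_index(h$stage1, blocks), 1)

  # finest level: every CRE its own cluster
  expect_equal(max(h$levels), 20)
  fin <- h$assignment[, which.max(h$levels)]
  expect_equal(length(unique(fin)), 20)

  # nesting: every finer cluster maps into exactly one coarser cluster
  for (l in seq_len(length(h$levels) - 1)) {
    co <- h$assignment[, l]; fi <- h$assignment[, l + 1]
    expect_true(all(tapply(co, fi, function(v) length(unique(v))) == 1))
  }

  # degenerate constant rows are kept, aligned, and clusterable
  x2 <- x; x2[3, ] <- 5
  expect_silent(h2 <- cluster_cres(x2, stage1_k = 4, seed = 7))
  expect_equal(nrow(h2$assignment), 20)
})

test_that("variance_explained matches its formula and stays in [0, 1]", {
  x <- matrix(c(1, 3, 1, 3), 2, 2)          # identical columns
  expect_equal(variance_explained(x), 1)
  xc <- rbind(c(1, 3), c(3, 1))             # mean profile constant
  expect_equal(variance_explained(xc), 0)
  # 2x2 hand value: a = (1.5, 3.5), abar = 2.5, ybar = 2.5
  xf <- rbind(c(1, 2), c(3, 4))
  num <- 2 * ((1.5 - 2.5)^2 + (3.5 - 2.5)^2)
  den <- sum((xf - 2.5)^2)
  expect_equal(variance_explained(xf), num / den)
  set.seed(9)
  for (i in 1:10) {
    z <- matrix(rnorm(24), 6, 4)
    v <- variance_explained(z)
    expect_gte(v, 0); expect_lte(v, 1)
  }
  expect_equal(variance_explained(matrix(2, 3, 3)), 0)
})
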