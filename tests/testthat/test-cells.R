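# Multi-cell pipeline: features, quantile normalization, filtering,
# clustering, pooling, end-to-end run.

test_that("cell features average normalized activity per CRE cluster", {
  # 5-bin genome, CREs at bins 1-3, clusters (1, 1, 2), two cells
  counts <- matrix(c(4L, 8L, 2L, 0L, 0L,
                     0L, 0L, 0L, 0L, 6L), 5, 2)
  fx <- build_cell_features(counts, catalog_bin_ids = 1:3,
                            stage1_labels = c(1L, 1L, 2L),
                            library_factors = c(2, 3))
  hand <- rbind(c(mean(log2(c(4, 8) / 2 + 1)), mean(log2(c(0, 0) / 3 + 1))),
                c(log2(2 / 2 + 1), log2(0 / 3 + 1)))
  expect_equal(unname(fx$features), unname(hand))
  # one-CRE cluster equals that CRE's normalized count; all-zero cell is 0
  expect_equal(unname(fx$features[2, 1]), log2(2))
  expect_true(all(fx$features[, 2] == 0))
})

test_that("quantile normalization matches hand fixture and is idempotent", {
  x <- cbind(c(1, 5, 3), c(2, 4, 8))
  qn <- quantile_normalize(x)
  ref <- (sort(x[, 1]) + sort(x[, 2])) / 2       # mean of sorted columns
  expect_equal(sort(qn[, 1]), ref)
  expect_equal(sort(qn[, 2]), ref)
  expect_equal(qn[order(x[, 1]), 1], ref)        # ranks preserved
  expect_equal(quantile_normalize(qn), qn)       # idempotent
  same <- cbind(c(1, 2, 9), c(1, 2, 9))
  expect_equal(quantile_normalize(same), same)   # identical columns unchanged
})

test_that("feature filtering applies the trend and the 10%-of-cells rule", {
  set.seed(43)
  n_cells <- 40; n_feat <- 50
  feats <- matrix(rnorm(n_feat * n_cells, sd = 0.1), n_feat, n_cells) +
    seq(0, 3, length.out = n_feat)               # spread of feature means
  feats[25, ] <- mean(feats[25, ]) + rnorm(n_cells, sd = 3)  # planted
  nonzero <- matrix(1, n_feat, n_cells)
  nonzero[3, ] <- c(rep(1, 2), rep(0, n_cells - 2))   # 5% of cells
  keep <- filter_features(feats, nonzero)
  expect_true(keep[25])
  expect_false(keep[3])                          # dropped regardless of SD

  # all features share one exact mean (rows are +/- patterns summing to
  # zero in floating point): the cubic trend collapses to the constant
  # mean SD, so only the high-SD half survives
  pat <- rep(c(-1, 1), n_cells / 2)
  f2 <- outer(rep(c(0.1, 2), 5), pat)
  k2 <- filter_features(f2, matrix(1, 10, n_cells))
  expect_true(all(k2[seq(2, 10, 2)]))
  expect_false(any(k2[seq(1, 9, 2)]))

  expect_warning(filter_features(matrix(rnorm(8), 2, 4),
                                 matrix(1, 2, 4)), "too few")
})

test_that("cluster_cells honors user labels, user k, and separates types", {
  set.seed(47)
  feats <- matrix(rnorm(30 * 20), 30, 20)
  lab_in <- rep(c("a", "b"), 10)
  cc <- cluster_cells(feats, user_labels = lab_in)
  expect_equal(cc$labels, as.integer(factor(lab_in)))
  expect_equal(cc$method, "user_labels")

  cc7 <- cluster_cells(feats, user_k = 7, seed = 2)
  expect_equal(cc7$n_clusters, 7)
  expect_error(cluster_cells(feats, user_k = 21), "exceeds")

  # two well-separated populations: default clustering recovers them
  truth <- rep(1:2, each = 25)
  sep <- matrix(rnorm(10 * 50), 10, 50) + 8 * outer(1:10 %% 2, truth)
  ccd <- cluster_cells(sep, seed = 3)
  expect_equal(adjusted_rand_index(ccd$labels, truth), 1)
})

test_that("pooling sums member cells and conserves reads", {
  set.seed(53)
  counts <- matrix(rpois(8 * 6, 2), 8, 6)
  labels <- c(1, 2, 1, 2, 2, 3)
  pc <- pool_cells(counts, labels)
  expect_equal(length(pc), 3)
  expect_equal(pc[[1]]$counts, rowSums(counts[, c(1, 3)]))
  expect_equal(pc[[3]]$counts, counts[, 6])           # singleton = the cell
  expect_equal(sum(sapply(pc, function(p) sum(p$counts))), sum(counts))
  expect_equal(pc[[2]]$L, sum(counts[, c(2, 4, 5)]) / 1e8)
})

test_that("reconstruct_population is deterministic and reduces to the single path", {
  sim <- simulate_compendium(n_bins = 600, n_samples = 25, n_clusters = 5,
                             seed = 61)
  comp <- build_compendium(sim$counts, stage1_k = 20, seed = 1)
  sc <- simulate_scatac(sim$truth, n_cells_per_type = c(12, 12),
                        reads_per_cell = 4000, seed = 62)
  res1 <- reconstruct_population(sc$counts, comp, user_k = 1, seed = 5)
  expect_equal(res1$clustering$n_clusters, 1)
  # user_k = 1 equals the single-pseudo-cell path on pooled counts
  pooled <- rowSums(sc$counts)
  direct <- reconstruct_cell(pooled, comp, L = sum(pooled) / 1e8, seed = 5)
  expect_equal(res1$fits[[1]]$recon$mu, direct$recon$mu)
  # rerun with the same seed is identical
  res2 <- reconstruct_population(sc$counts, comp, user_k = 1, seed = 5)
  expect_identical(res1$fits[[1]]$recon$mu, res2$fits[[1]]$recon$mu)
})
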