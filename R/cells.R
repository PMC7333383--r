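# Multi-cell pipeline: per-cell features on stage-1 CRE clusters, quantile
# normalization, variability filtering, dimension reduction + model-based
# clustering, pseudo-cell pooling, and the end-to-end multi-cell run.

#' Per-cell features on CRE clusters
#'
#' For each cell, the average normalized activity `log2(y / L_c + 1)` of the
#' CREs in each stage-1 cluster (the level-5000 clustering at full scale) is
#' a feature; `L_c` is the cell's total read count / 1e8.
#'
#' @param cell_counts matrix of counts over all genome bins, bins x cells.
#' @param catalog_bin_ids genome-bin row ids of the catalog CREs.
#' @param stage1_labels stage-1 cluster label per catalog CRE.
#' @param library_factors optional per-cell `L_c` (default from totals).
#' @return A `cell_feature_matrix`: list with `features` (clusters x cells),
#'   `cluster_ids`, `library_factors`, and `cluster_nonzero` (clusters x
#'   cells, raw summed counts; used by the 10%-of-cells rule).
#' @export
build_cell_features <- function(cell_counts, catalog_bin_ids, stage1_labels,
                                library_factors = NULL) {
  cell_counts <- as.matrix(cell_counts)
  L <- library_factors %||% (colSums(cell_counts) / 1e8)
  L[L == 0] <- 1
  y <- cell_counts[catalog_bin_ids, , drop = FALSE]
  norm <- log2(sweep(y, 2, L, "/") + 1)
  sizes <- as.vector(table(stage1_labels))
  feats <- rowsum(norm, stage1_labels) / sizes
  rawsum <- rowsum(y, stage1_labels)
  structure(list(features = feats, cluster_ids = sort(unique(stage1_labels)),
                 library_factors = L, cluster_nonzero = rawsum),
            class = "cell_feature_matrix")
}

#' Quantile normalize features across cells
#'
#' After normalization, every cell's sorted feature vector equals the mean of
#' the sorted columns; ties are averaged.
#'
#' @param features numeric matrix, features x cells.
#' @return matrix of the same shape.
#' @export
quantile_normalize <- function(features) {
  out <- limma::normalizeQuantiles(as.matrix(features), ties = TRUE)
  dimnames(out) <- dimnames(features)
  out
}

#' Filter low-variability and low-coverage features
#'
#' Per feature, the mean and SD across cells are computed; a cubic
#' polynomial of SD on mean is fit by ordinary least squares, and features
#' whose observed SD does not exceed the fitted SD are dropped. Among the
#' survivors, only features whose CRE cluster has a nonzero summed read
#' count in at least `min_cells_frac` of cells are retained.
#'
#' @param features matrix (typically quantile-normalized), features x cells.
#' @param cluster_nonzero raw summed counts per feature per cell (from
#'   [build_cell_features()]).
#' @param min_cells_frac minimum fraction of cells with reads (default 0.1).
#' @return logical mask over features.
#' @export
filter_features <- function(features, cluster_nonzero,
                            min_cells_frac = 0.1) {
  mu <- rowMeans(features)
  sdv <- apply(features, 1, sd)
  if (nrow(features) >= 4) {
    # fitted() tolerates a rank-deficient design (e.g. all means equal,
    # where the cubic collapses to the constant mean SD)
    fit <- lm(sdv ~ poly(mu, 3, raw = TRUE))
    keep_var <- sdv > fitted(fit)
  } else {
    warning("too few features for the polynomial trend; keeping all")
    keep_var <- rep(TRUE, nrow(features))
  }
  frac_nonzero <- rowMeans(cluster_nonzero > 0)
  keep_var & (frac_nonzero >= min_cells_frac)
}

#' Cluster cells
#'
#' PCA on retained features (top `n_pcs` components), a 2-D embedding (the
#' first two principal components), then Gaussian-mixture model-based
#' clustering on the embedding with the component count (1..20) and
#' covariance family (full vs diagonal) chosen by BIC. Alternatively, a
#' fixed component count (`user_k`) or externally supplied labels
#' (`user_labels`) can be used.
#'
#' @param features retained feature matrix, features x cells.
#' @param n_pcs number of principal components (default 50, capped at rank).
#' @param seed RNG seed.
#' @param user_k optional fixed number of clusters.
#' @param user_labels optional externally supplied labels (pass-through).
#' @return A `cell_clustering`: list with `labels`, `n_clusters`, `method`,
#'   `embedding` (cells x 2), `pcs`.
#' @export
cluster_cells <- function(features, n_pcs = 50, seed = 1, user_k = NULL,
                          user_labels = NULL) {
  n_cells <- ncol(features)
  if (n_cells < 2) stop("need at least 2 cells")
  if (!is.null(user_labels)) {
    stopifnot(length(user_labels) == n_cells)
    lab <- as.integer(factor(user_labels))
    return(structure(list(labels = lab,
                          n_clusters = length(unique(lab)),
                          method = "user_labels", embedding = NULL,
                          pcs = NULL),
                     class = "cell_clustering"))
  }
  if (!is.null(user_k) && user_k > n_cells)
    stop("user_k exceeds the number of cells")
  x <- t(as.matrix(features))
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  k <- min(n_pcs, ncol(pc$x))
  pcs <- pc$x[, seq_len(k), drop = FALSE]
  emb <- if (ncol(pcs) >= 2) pcs[, 1:2] else cbind(pcs[, 1], 0)
  if (!is.null(user_k)) {
    fit <- tryCatch(gmm_select(emb, G_range = user_k, seed = seed),
                    error = function(e) NULL)
    if (is.null(fit) || length(unique(fit$labels)) != user_k) {
      set.seed(seed)   # mixture degenerate at this k: fall back to k-means
      fit <- list(labels = kmeans(emb, centers = user_k,
                                  nstart = 10)$cluster)
    }
    method <- "user_k"
  } else {
    fit <- gmm_select(emb, G_range = seq_len(min(20, n_cells - 1)),
                      seed = seed)
    method <- "default"
  }
  lab <- as.integer(factor(fit$labels))
  structure(list(labels = lab, n_clusters = length(unique(lab)),
                 method = method, embedding = emb, pcs = pcs),
            class = "cell_clustering")
}

#' Pool cells of each cluster into a pseudo-cell
#'
#' @param cell_counts matrix, bins x cells.
#' @param labels cluster label per cell.
#' @return list of `pseudo_cell`s: each has `counts` (per-bin sums), `L`
#'   (pooled total / 1e8), `members` (cell column indices).
#' @export
pool_cells <- function(cell_counts, labels) {
  cell_counts <- as.matrix(cell_counts)
  stopifnot(length(labels) == ncol(cell_counts))
  lapply(sort(unique(labels)), function(k) {
    members <- which(labels == k)
    cnt <- rowSums(cell_counts[, members, drop = FALSE])
    structure(list(counts = cnt, L = sum(cnt) / 1e8, members = members,
                   cluster = k),
              class = "pseudo_cell")
  })
}

#' Full multi-cell pipeline
#'
#' Builds per-cell features on the stage-1 CRE clusters, quantile-normalizes
#' and filters them, clusters the cells (unless labels are supplied), pools
#' each cluster into a pseudo-cell, and fits the single-cell model (bias
#' spline, cross-validated K, reconstruction) to each pseudo-cell;
#' optionally extends each reconstruction genome-wide.
#'
#' @param cell_counts matrix, genome bins x cells.
#' @param compendium a `regulome_compendium`.
#' @param user_k,user_labels forwarded to [cluster_cells()].
#' @param candidates candidate K levels for cross-validation.
#' @param postprocess if TRUE, also build the genome-wide track per cluster.
#' @param seed RNG seed.
#' @return list with `clustering` and `fits` (one [reconstruct_cell()] result
#'   per cell cluster, each with its `pseudo_cell` and, if requested,
#'   `track`).
#' @export
reconstruct_population <- function(cell_counts, compendium, user_k = NULL,
                      user_labels = NULL, candidates = NULL,
                      postprocess = FALSE, seed = 1) {
  cell_counts <- as.matrix(cell_counts)
  feats <- build_cell_features(cell_counts, compendium$catalog$bin_ids,
                               compendium$hierarchy$stage1)
  qn <- quantile_normalize(feats$features)
  keep <- filter_features(qn, feats$cluster_nonzero)
  if (!any(keep)) keep <- rep(TRUE, nrow(qn))
  clustering <- cluster_cells(qn[keep, , drop = FALSE], seed = seed,
                              user_k = user_k, user_labels = user_labels)
  pseudo <- pool_cells(cell_counts, clustering$labels)
  fits <- lapply(pseudo, function(pc) {
    fit <- reconstruct_cell(pc$counts, compendium, L = pc$L,
                          candidates = candidates, seed = seed)
    fit$pseudo_cell <- pc
    if (postprocess)
      fit$track <- predict_noncre_bins(pc$counts, pc$L,
                                       compendium$effects_genome,
                                       fit$recon, compendium$catalog$bin_ids,
                                       compendium$index, seed = seed)
    fit
  })
  list(clustering = clustering, fits = fits)
}
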