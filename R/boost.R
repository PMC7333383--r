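# Histogram-based gradient-boosted regression trees (squared loss). Used by
# the genome-wide post-processing step; kept in-package because no boosting
# library is available in the target environment. The algorithm is
# deterministic (no row/column subsampling), so fits are bit-reproducible.

# grow one regression tree on pre-binned features; returns a node table
grow_tree <- function(binids, r, n_bins, max_depth, min_node) {
  nodes <- list()
  new_node <- function() length(nodes) + 1L
  # stack of (row index vector, depth, node slot)
  root <- new_node()
  nodes[[root]] <- list(leaf = TRUE, value = mean(r))
  stack <- list(list(rows = seq_along(r), depth = 0L, id = root))
  while (length(stack)) {
    item <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    rows <- item$rows
    nodes[[item$id]]$value <- mean(r[rows])
    if (item$depth >= max_depth || length(rows) < 2 * min_node) next
    rr <- r[rows]
    tot_s <- sum(rr); tot_n <- length(rr)
    base <- tot_s^2 / tot_n
    best <- list(gain = 1e-10)
    for (f in seq_len(ncol(binids))) {
      b <- binids[rows, f]
      cnt <- tabulate(b, n_bins)
      sm <- numeric(n_bins)
      agg <- rowsum(rr, b)
      sm[as.integer(rownames(agg))] <- agg
      cn <- cumsum(cnt); cs <- cumsum(sm)
      nl <- cn[-n_bins]; sl <- cs[-n_bins]
      nr <- tot_n - nl; sr <- tot_s - sl
      valid <- nl >= min_node & nr >= min_node
      if (!any(valid)) next
      gain <- ifelse(valid, sl^2 / pmax(nl, 1) + sr^2 / pmax(nr, 1) - base,
                     -Inf)
      j <- which.max(gain)
      if (gain[j] > best$gain) best <- list(gain = gain[j], f = f, bin = j)
    }
    if (is.null(best$f)) next
    go_left <- binids[rows, best$f] <= best$bin
    lid <- new_node(); nodes[[lid]] <- list(leaf = TRUE, value = 0)
    rid <- new_node(); nodes[[rid]] <- list(leaf = TRUE, value = 0)
    nodes[[item$id]] <- list(leaf = FALSE, f = best$f, bin = best$bin,
                             left = lid, right = rid,
                             value = nodes[[item$id]]$value)
    stack[[length(stack) + 1L]] <- list(rows = rows[go_left],
                                        depth = item$depth + 1L, id = lid)
    stack[[length(stack) + 1L]] <- list(rows = rows[!go_left],
                                        depth = item$depth + 1L, id = rid)
  }
  nodes
}

tree_predict <- function(nodes, binids) {
  out <- numeric(nrow(binids))
  walk <- function(id, rows) {
    nd <- nodes[[id]]
    if (nd$leaf) { out[rows] <<- nd$value; return(invisible()) }
    go_left <- binids[rows, nd$f] <= nd$bin
    if (any(go_left)) walk(nd$left, rows[go_left])
    if (any(!go_left)) walk(nd$right, rows[!go_left])
  }
  walk(1L, seq_len(nrow(binids)))
  out
}

#' Fit gradient-boosted regression trees
#'
#' Squared-error boosting with histogram splits: each feature is discretized
#' once into at most `n_feature_bins` quantile bins, and each tree greedily
#' splits on the binned values. Deterministic given the data.
#'
#' @param X numeric feature matrix.
#' @param y numeric response.
#' @param n_trees number of trees (default 100).
#' @param max_depth tree depth (default 4).
#' @param learning_rate shrinkage (default 0.1).
#' @param n_feature_bins histogram resolution (default 64).
#' @param min_node minimum observations per child (default 10).
#' @return A `gbt_model`.
#' @export
gbt_fit <- function(X, y, n_trees = 100, max_depth = 4, learning_rate = 0.1,
                    n_feature_bins = 64, min_node = 10) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), all(is.finite(X)), all(is.finite(y)))
  breaks <- lapply(seq_len(ncol(X)), function(f) {
    b <- unique(quantile(X[, f], probs = seq_len(n_feature_bins - 1) /
                           n_feature_bins, names = FALSE))
    b[is.finite(b)]
  })
  binids <- sapply(seq_len(ncol(X)), function(f)
    findInterval(X[, f], breaks[[f]]) + 1L)
  binids <- matrix(as.integer(binids), nrow = nrow(X))
  nb <- n_feature_bins
  base <- mean(y)
  pred <- rep(base, length(y))
  trees <- vector("list", n_trees)
  mn <- min(min_node, max(1L, floor(length(y) / 4)))
  for (t in seq_len(n_trees)) {
    r <- y - pred
    tr <- grow_tree(binids, r, nb, max_depth, mn)
    trees[[t]] <- tr
    pred <- pred + learning_rate * tree_predict(tr, binids)
  }
  structure(list(base = base, trees = trees, breaks = breaks,
                 learning_rate = learning_rate),
            class = "gbt_model")
}

#' @rdname gbt_fit
#' @param model a `gbt_model`.
#' @param newX feature matrix to predict for.
#' @export
gbt_predict <- function(model, newX) {
  newX <- as.matrix(newX)
  binids <- sapply(seq_along(model$breaks), function(f)
    findInterval(newX[, f], model$breaks[[f]]) + 1L)
  binids <- matrix(as.integer(binids), nrow = nrow(newX))
  pred <- rep(model$base, nrow(newX))
  for (tr in model$trees)
    pred <- pred + model$learning_rate * tree_predict(tr, binids)
  pred
}
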