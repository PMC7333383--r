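# Small Gaussian-mixture engine for model-based cell clustering on a 2-D
# embedding: EM with full or diagonal covariance, component count chosen by
# BIC. Kept in-package because no mixture-model package is available in the
# target environment.

dmvnorm_log <- function(x, mean, sigma) {
  d <- ncol(x)
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ch)) return(rep(-Inf, nrow(x)))
  z <- forwardsolve(t(ch), t(x) - mean)
  -0.5 * d * log(2 * pi) - sum(log(diag(ch))) - 0.5 * colSums(z^2)
}

gmm_em <- function(x, G, family = c("full", "diag"), seed = 1,
                   max_iter = 200, tol = 1e-8) {
  family <- match.arg(family)
  x <- as.matrix(x)
  n <- nrow(x); d <- ncol(x)
  if (G == 1) {
    mu <- colMeans(x)
    sig <- crossprod(sweep(x, 2, mu)) / n + diag(1e-8, d)
    if (family == "diag") sig <- diag(diag(sig), d)
    ll <- sum(dmvnorm_log(x, mu, sig))
    npar <- d + if (family == "full") d * (d + 1) / 2 else d
    return(list(loglik = ll, bic = -2 * ll + npar * log(n),
                labels = rep(1L, n), G = 1, family = family,
                means = matrix(mu, 1), weights = 1))
  }
  set.seed(seed)
  km <- tryCatch(kmeans(x, centers = G, nstart = 5, iter.max = 50),
                 error = function(e) NULL)
  if (is.null(km)) return(list(bic = Inf, loglik = -Inf))
  z <- km$cluster
  w <- as.vector(table(factor(z, levels = seq_len(G)))) / n
  mus <- lapply(seq_len(G), function(g)
    if (any(z == g)) colMeans(x[z == g, , drop = FALSE]) else colMeans(x))
  glob <- crossprod(sweep(x, 2, colMeans(x))) / n + diag(1e-6, d)
  sigs <- lapply(seq_len(G), function(g) glob)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    logp <- sapply(seq_len(G), function(g)
      log(w[g] + 1e-300) + dmvnorm_log(x, mus[[g]], sigs[[g]]))
    mx <- apply(logp, 1, max)
    pr <- exp(logp - mx)
    tot <- rowSums(pr)
    ll <- sum(mx + log(tot))
    resp <- pr / tot
    nk <- colSums(resp)
    if (any(nk < d + 1)) return(list(bic = Inf, loglik = -Inf))
    w <- nk / n
    for (g in seq_len(G)) {
      mus[[g]] <- colSums(resp[, g] * x) / nk[g]
      xc <- sweep(x, 2, mus[[g]])
      S <- crossprod(xc * sqrt(resp[, g])) / nk[g] + diag(1e-8, d)
      sigs[[g]] <- if (family == "diag") diag(diag(S), d) else S
    }
    if (abs(ll - ll_old) < tol * (1 + abs(ll))) break
    ll_old <- ll
  }
  npar <- (G - 1) + G * d + G * (if (family == "full") d * (d + 1) / 2
                                 else d)
  list(loglik = ll, bic = -2 * ll + npar * log(n),
       labels = apply(resp, 1, which.max), G = G, family = family,
       means = do.call(rbind, mus), weights = w)
}

# scan component counts (and covariance families) by BIC
gmm_select <- function(x, G_range = 1:20, families = c("full", "diag"),
                       seed = 1) {
  best <- NULL
  for (family in families) for (G in G_range) {
    if (G >= nrow(x)) next
    fit <- gmm_em(x, G, family, seed = seed)
    if (!is.finite(fit$bic)) next
    if (is.null(best) || fit$bic < best$bic) best <- fit
  }
  if (is.null(best)) stop("no GMM fit converged")
  best
}

#' Adjusted Rand index between two labelings
#'
#' @param a,b vectors of cluster labels of equal length.
#' @return ARI in [-1, 1]; 1 means identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  expected <- si * sj / n
  mx <- (si + sj) / 2
  if (mx == expected) return(1)
  (sij - expected) / (mx - expected)
}
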