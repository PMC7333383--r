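# Monotone I-spline basis, built as suffix sums of a B-spline basis with the
# same interior knots: with degree-d B-splines B_1..B_n on boundary knots of
# multiplicity d+1, the functions I_j = sum_{m>j} B_m (j = 1..n-1) are
# non-decreasing, run from 0 to 1 across the training range, and span (with
# an intercept) the full spline space. Basis count = #interior knots + degree.

#' Evaluate an I-spline basis
#'
#' @param x evaluation points (clamped to `boundary` for basis evaluation;
#'   extrapolation is handled by [evaluate_bias()]).
#' @param interior interior knot positions (may be empty).
#' @param boundary length-2 range `c(a, b)` with `a < b`.
#' @param degree spline degree (1..3; default 3, cubic).
#' @return matrix `length(x)` x `(length(interior) + degree)`, each column a
#'   monotone non-decreasing basis function with values in [0, 1].
#' @export
ispline_basis <- function(x, interior, boundary, degree = 3) {
  stopifnot(degree >= 1, boundary[1] < boundary[2])
  interior <- sort(as.numeric(interior))
  kv <- c(rep(boundary[1], degree + 1), interior, rep(boundary[2], degree + 1))
  xc <- pmin(pmax(x, boundary[1]), boundary[2])
  B <- splines::splineDesign(kv, xc, ord = degree + 1)
  n <- ncol(B)
  out <- matrix(0, length(x), n - 1)
  acc <- numeric(length(x))
  for (j in n:2) {
    acc <- acc + B[, j]
    out[, j - 1] <- acc
  }
  out
}

# quantile-based interior knots for a candidate basis size T:
# knots at the t/T-th quantiles of the training values, t = 1..T-1
bias_knots <- function(m, T) {
  if (T <= 1) return(numeric(0))
  q <- quantile(m, probs = seq_len(T - 1) / T, names = FALSE)
  b <- range(m)
  q <- q[q > b[1] & q < b[2]]
  unique(q)
}

new_bias_spline <- function(alpha0, alpha, interior, boundary, degree, T,
                            loglik, n, degenerate = FALSE) {
  structure(list(alpha0 = alpha0, alpha = alpha, knots = interior,
                 boundary = boundary, degree = degree, T = T,
                 loglik = loglik, n = n, degenerate = degenerate),
            class = "bias_spline")
}

#' Evaluate the technical-bias function h(x)
#'
#' Inside the training range the monotone spline is evaluated directly;
#' outside it, h continues linearly with the one-sided boundary slope (which
#' is non-negative by construction).
#'
#' @param spline a `bias_spline` from [fit_bias_function()].
#' @param x evaluation points.
#' @return h(x), non-decreasing in x.
#' @export
evaluate_bias <- function(spline, x) {
  if (spline$degenerate || length(spline$alpha) == 0)
    return(rep(spline$alpha0, length(x)))
  a <- spline$boundary[1]; b <- spline$boundary[2]
  eps <- (b - a) * 1e-6
  val <- function(z)
    spline$alpha0 + drop(ispline_basis(z, spline$knots, spline$boundary,
                                       spline$degree) %*% spline$alpha)
  out <- val(x)
  lo <- x < a; hi <- x > b
  if (any(lo)) {
    slope <- (val(a + eps) - val(a)) / eps
    out[lo] <- val(a) + slope * (x[lo] - a)
  }
  if (any(hi)) {
    slope <- (val(b) - val(b - eps)) / eps
    out[hi] <- val(b) + slope * (x[hi] - b)
  }
  out
}

#' Fit the cell-specific technical-bias function
#'
#' Models the map from bulk-scale log activity to single-cell-scale log
#' activity at low-variability CREs, whose activity in any cell is taken to
#' be their compendium baseline `m`. For each candidate basis size T in
#' `T_candidates`, interior knots are placed at the t/T-th quantiles of `m`
#' (t = 1..T-1), and the Poisson log-likelihood
#' `sum_i [y_i h(m_i) - L exp(h(m_i))]` is maximized over the intercept
#' (unconstrained) and basis coefficients (constrained >= 0, making h
#' non-decreasing). The T with the smallest BIC
#' (`-2 loglik + (n_basis + 1) log n`) is returned.
#'
#' @param y read counts of the (pseudo-)cell at the low-variability CREs.
#' @param m baseline means of those CREs (natural-log scale).
#' @param L the cell's library factor (> 0).
#' @param T_candidates candidate basis sizes (default 1:6).
#' @param degree spline degree (default 3, cubic).
#' @return A `bias_spline`; the per-T fit table is attached as attribute
#'   `"fits"`.
#' @export
fit_bias_function <- function(y, m, L, T_candidates = 1:6, degree = 3) {
  stopifnot(length(y) == length(m), L > 0)
  ok <- is.finite(m)
  y <- y[ok]; m <- m[ok]
  n <- length(y)
  if (n < 10) stop("need at least 10 low-variability CREs with finite m")
  if (sum(y) == 0) {
    warning("all counts zero at low-variability CREs; returning flat bias")
    return(new_bias_spline(-20, numeric(0), numeric(0), range(m), degree,
                           min(T_candidates), -Inf, n, degenerate = TRUE))
  }
  if (diff(range(m)) < 1e-8) {
    warning("degenerate baseline range; returning flat bias")
    return(new_bias_spline(log(mean(y) / L), numeric(0), numeric(0),
                           c(m[1] - 1, m[1] + 1), degree, min(T_candidates),
                           sum(y * log(mean(y) / L)) - sum(y), n,
                           degenerate = TRUE))
  }
  bnd <- range(m)
  fits <- list()
  diag_tab <- data.frame()
  for (T in T_candidates) {
    interior <- bias_knots(m, T)
    B <- ispline_basis(m, interior, bnd, degree)
    nb <- ncol(B)
    X <- cbind(1, B)
    negll <- function(par) {
      eta <- drop(X %*% par)
      sum(L * exp(eta)) - sum(y * eta)
    }
    grad <- function(par) {
      eta <- drop(X %*% par)
      drop(crossprod(X, L * exp(eta) - y))
    }
    init <- c(log(sum(y) / (L * n)), rep(0.01, nb))
    fit <- tryCatch(
      optim(init, negll, grad, method = "L-BFGS-B",
            lower = c(-Inf, rep(0, nb)),
            control = list(maxit = 500, factr = 1e5)),
      error = function(e) NULL)
    ok_fit <- !is.null(fit) && is.finite(fit$value)
    ll <- if (ok_fit) -fit$value else NA_real_
    bic <- if (ok_fit) -2 * ll + (nb + 1) * log(n) else Inf
    diag_tab <- rbind(diag_tab,
                      data.frame(T = T, n_basis = nb, loglik = ll, bic = bic,
                                 converged = ok_fit &&
                                   fit$convergence == 0))
    if (ok_fit)
      fits[[as.character(T)]] <-
        new_bias_spline(fit$par[1], fit$par[-1], interior, bnd, degree, T,
                        ll, n)
  }
  if (length(fits) == 0)
    stop(paste("bias-function optimizer failed at every T;",
               paste(capture.output(print(diag_tab)), collapse = "\n")))
  best <- which.min(diag_tab$bic)     # ties: first, i.e. smallest T
  out <- fits[[as.character(diag_tab$T[best])]]
  attr(out, "fits") <- diag_tab
  out
}
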