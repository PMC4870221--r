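# Spatial machinery: first-nearest-neighbour weights, maximum-likelihood
# SAR-error fitting via the concentrated log-likelihood with an eigenvalue
# log-determinant, Nagelkerke pseudo-R2, and Dutilleul's corrected
# correlation.

#' First-nearest-neighbour spatial weights
#'
#' Links every cell to its single nearest neighbour (Euclidean distance on
#' projected km coordinates), symmetrizes (i ~ j if either is the other's
#' nearest neighbour; ties broken towards the lowest index), and
#' row-standardizes. Symmetrization guarantees no isolated node.
#'
#' @param coords `data.frame` or matrix with columns `x`, `y` (km); no
#'   duplicate coordinates allowed.
#' @param rule Neighbour rule; only `"knn1"` is implemented.
#' @return List of class `spatial_weights`: row-standardized sparse `W`,
#'   binary symmetric adjacency `A`, `n`, real eigenvalues `eigenvalues` of
#'   `W` (via the similar symmetric matrix), and metadata.
#' @export
build_weights <- function(coords, rule = "knn1") {
  rule <- match.arg(rule)
  coords <- as.data.frame(coords)
  n <- nrow(coords)
  if (n < 2L) stop("at least 2 cells required")
  D <- as.matrix(dist(coords[, c("x", "y")]))
  if (any(D[upper.tri(D)] < 1e-12)) stop("duplicate coordinates")
  diag(D) <- Inf
  nn <- max.col(-D, ties.method = "first")
  A <- Matrix::sparseMatrix(i = seq_len(n), j = nn, x = 1, dims = c(n, n))
  A <- (A + Matrix::t(A) > 0) * 1  # symmetrize
  deg <- Matrix::rowSums(A)
  stopifnot(all(deg > 0))  # impossible after symmetrization
  W <- Matrix::Diagonal(x = 1 / deg) %*% A
  # W = D^-1 A is similar to the symmetric D^-1/2 A D^-1/2: real eigenvalues
  S <- Matrix::Diagonal(x = 1 / sqrt(deg)) %*% A %*%
    Matrix::Diagonal(x = 1 / sqrt(deg))
  ev <- eigen(as.matrix(S), symmetric = TRUE, only.values = TRUE)$values
  structure(list(W = methods::as(W, "CsparseMatrix"), A = A, n = n,
                 eigenvalues = ev, rule = rule, row_standardized = TRUE),
            class = "spatial_weights")
}

#' @export
print.spatial_weights <- function(x, ...) {
  cat("spatial_weights:", x$n, "cells, rule =", x$rule,
      ", row-standardized;", Matrix::nnzero(x$A) / 2, "links\n")
  invisible(x)
}

#' Log-determinant of (I - lambda W) via the eigenvalue spectrum
#'
#' @param W A [build_weights()] object.
#' @param lambda Autoregressive parameter.
#' @return `log |I - lambda W|`.
#' @export
sar_log_det <- function(W, lambda) sum(log(1 - lambda * W$eigenvalues))

# concentrated log-likelihood pieces at a given lambda
sar_profile <- function(lambda, y, X, Wy, WX, W, n) {
  Ay <- y - lambda * Wy
  AX <- X - lambda * WX
  fit <- lm.fit(AX, Ay)
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / n
  ll <- -n / 2 * (log(2 * pi) + 1 + log(sigma2)) + sar_log_det(W, lambda)
  list(ll = ll, beta = fit$coefficients, sigma2 = sigma2, rss = rss)
}

#' Maximum-likelihood SAR-error model
#'
#' Fits `y = X beta + u`, `u = lambda W u + eps`, `eps ~ N(0, sigma2 I)` by
#' maximizing the log-likelihood concentrated over `lambda` on
#' `(-0.999, 0.999)` with bounded scalar optimization; for each `lambda`,
#' `beta` and `sigma2` come from least squares on the spatially filtered
#' system `(I - lambda W) y`, `(I - lambda W) X`. The log-determinant term
#' uses the precomputed eigenvalue spectrum of `W`. The AIC parameter count
#' is `ncol(X) + 2` (coefficients including the intercept, plus `lambda` and
#' `sigma2`).
#'
#' @param X Design matrix including an intercept column; full column rank,
#'   non-intercept columns non-constant.
#' @param y Response vector.
#' @param W A [build_weights()] object.
#' @param lambda Fix the autoregressive parameter at this value instead of
#'   estimating it (e.g. `lambda = 0` reproduces OLS).
#' @param interval Search interval for `lambda`.
#' @return List of class `sar_fit`: `coefficients`, `lambda`, `sigma2`,
#'   `logLik`, `aic`, `n`, `k`, raw trend `residuals` (`y - X beta`),
#'   `fitted`, and a `boundary` flag set when the optimizer stopped at the
#'   edge of the interval.
#' @export
fit_sar_error <- function(X, y, W, lambda = NULL,
                          interval = c(-0.999, 0.999)) {
  X <- as.matrix(X)
  n <- length(y)
  if (nrow(X) != n || W$n != n) stop("dimension mismatch")
  p <- ncol(X)
  if (n <= p + 2L) stop("more parameters than observations")
  # a constant column next to the intercept is collinear, so the rank test
  # also covers the non-constant-column requirement
  if (qr(X)$rank < p) stop("rank-deficient design matrix")

  Wy <- as.vector(W$W %*% y)
  WX <- as.matrix(W$W %*% X)
  boundary <- FALSE
  if (is.null(lambda)) {
    opt <- optimize(function(l) sar_profile(l, y, X, Wy, WX, W, n)$ll,
                    interval = interval, maximum = TRUE)
    lambda <- opt$maximum
    if (min(abs(lambda - interval)) < 1e-4) {
      warning("lambda estimate at the search boundary")
      boundary <- TRUE
    }
  }
  prof <- sar_profile(lambda, y, X, Wy, WX, W, n)
  k <- p + 2L
  beta <- prof$beta
  names(beta) <- colnames(X)
  fitted <- as.vector(X %*% beta)
  structure(list(coefficients = beta, lambda = lambda, sigma2 = prof$sigma2,
                 logLik = prof$ll, aic = 2 * k - 2 * prof$ll, n = n, k = k,
                 residuals = y - fitted, fitted = fitted,
                 boundary = boundary),
            class = "sar_fit")
}

#' @export
print.sar_fit <- function(x, ...) {
  cat("SAR-error fit: n =", x$n, ", lambda =", signif(x$lambda, 4),
      ", sigma2 =", signif(x$sigma2, 4), ", logLik =", signif(x$logLik, 6),
      ", AIC =", signif(x$aic, 6), "\n")
  print(signif(x$coefficients, 4))
  invisible(x)
}

#' Nagelkerke pseudo-R2 of a fitted model against the intercept-only null
#'
#' `R2_CS = 1 - exp(-(2/n) (L1 - L0))`, normalized by its maximum
#' `1 - exp((2/n) L0)` (Nagelkerke 1991) and clipped to `[0, 1)`. The null is
#' the intercept-only SAR-error model on the same response and weights, so
#' the statistic isolates the predictor contribution from spatial structure.
#'
#' @param fit,null_fit [fit_sar_error()] objects sharing `y`, `n`, `W`.
#' @return Pseudo-R2 in `[0, 1)`; floored at 0 with a warning when the full
#'   model's likelihood falls below the null's (optimizer failure).
#' @export
nagelkerke_r2 <- function(fit, null_fit) {
  if (fit$n != null_fit$n) stop("fits must share n")
  n <- fit$n
  L1 <- fit$logLik
  L0 <- null_fit$logLik
  if (L1 < L0 - 1e-8) warning("full-model likelihood below the null's")
  r2_cs <- 1 - exp(-(2 / n) * (L1 - L0))
  r2 <- r2_cs / (1 - exp((2 / n) * L0))
  min(max(r2, 0), 1 - 1e-12)
}

#' Dutilleul-corrected correlation between two spatial variables
#'
#' Pearson correlation with the effective sample size of Dutilleul (1993):
#' spatial correlation matrices of both variables are estimated from
#' distance-class Moran coefficients, and the corrected degrees of freedom
#' follow from `M = 1 + tr(B Sx) tr(B Sy) / tr(B Sx B Sy)` with `B` the
#' centring matrix; the t test uses `M - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors (length >= 10, non-degenerate variance).
#' @param coords `data.frame`/matrix of projected `x`, `y` coordinates (km).
#' @param nclass Number of equal-width distance classes.
#' @return List: `r`, `effective_n`, `df`, `t`, `p` (corrected), and
#'   `p_uncorrected` (naive t test with `n - 2` df).
#' @export
dutilleul_cor <- function(x, y, coords, nclass = 13L) {
  n <- length(x)
  if (n < 10L || length(y) != n) stop("need two vectors of length >= 10")
  if (var(x) == 0 || var(y) == 0) stop("degenerate variance")
  D <- as.matrix(dist(as.data.frame(coords)[, c("x", "y")]))
  ut <- D[upper.tri(D)]
  brks <- seq(0, max(ut), length.out = nclass + 1L)
  xc <- x - mean(x); yc <- y - mean(y)
  sxx <- sum(xc^2); syy <- sum(yc^2)
  Sx <- diag(n); Sy <- diag(n)
  for (k in seq_len(nclass)) {
    Wk <- (D > brks[k] & D <= brks[k + 1L]) * 1
    s0 <- sum(Wk)
    if (s0 == 0) next
    Ix <- (n / s0) * as.numeric(crossprod(xc, Wk %*% xc)) / sxx
    Iy <- (n / s0) * as.numeric(crossprod(yc, Wk %*% yc)) / syy
    Sx <- Sx + Ix * Wk
    Sy <- Sy + Iy * Wk
  }
  B <- diag(n) - 1 / n
  BSx <- B %*% Sx
  BSy <- B %*% Sy
  M <- 1 + sum(diag(BSx)) * sum(diag(BSy)) / sum(BSx * t(BSy))
  r <- cor(x, y)
  df <- M - 2
  tstat <- r * sqrt(df / (1 - r^2))
  p <- 2 * pt(-abs(tstat), df)
  t0 <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, effective_n = M, df = df, t = tstat, p = p,
       p_uncorrected = 2 * pt(-abs(t0), n - 2))
}
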