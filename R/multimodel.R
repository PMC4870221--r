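# Exhaustive multimodel inference: enumeration of linear/unimodal predictor
# combinations, Akaike weights, per-variable importance (W_AIC),
# conditional model-averaged standardized coefficients, and partial
# residuals.

.shape_levels <- c("absent", "linear", "unimodal")

#' Enumerate all linear/unimodal model specifications
#'
#' Full factorial over shapes `absent`, `linear`, `unimodal` (linear +
#' quadratic) per predictor — `3^p` models including the intercept-only one —
#' in deterministic lexicographic order, optionally truncated to models with
#' at most `max_predictors` included predictors.
#'
#' @param predictors Character vector of predictor names.
#' @param max_predictors Optional cap on the number of included predictors.
#' @return List of specs; each is an integer vector named by predictor with
#'   values 0 (absent), 1 (linear), 2 (unimodal).
#' @export
enumerate_models <- function(predictors, max_predictors = NULL) {
  p <- length(predictors)
  if (p < 1L) stop("at least one predictor required")
  if (p > 12L && is.null(max_predictors))
    warning("3^", p, " models without a cap; consider max_predictors")
  grid <- do.call(expand.grid,
                  c(rep(list(0:2), p), KEEP.OUT.ATTRS = FALSE))
  grid <- grid[, rev(seq_len(p)), drop = FALSE]  # lexicographic in input order
  names(grid) <- predictors
  grid <- grid[do.call(order, grid), , drop = FALSE]
  specs <- lapply(seq_len(nrow(grid)), function(i) {
    s <- as.integer(grid[i, ])
    names(s) <- predictors
    s
  })
  if (!is.null(max_predictors))
    specs <- Filter(function(s) sum(s > 0L) <= max_predictors, specs)
  specs
}

#' Akaike weights
#'
#' `w_i = exp(-Delta_i / 2) / sum_j exp(-Delta_j / 2)` with
#' `Delta_i = AIC_i - min(AIC)`.
#'
#' @param aics Finite numeric vector of AIC values.
#' @return Weights summing to 1.
#' @export
akaike_weights <- function(aics) {
  if (any(!is.finite(aics))) stop("AIC values must be finite")
  d <- aics - min(aics)
  w <- exp(-d / 2)
  w / sum(w)
}

#' Per-variable relative support (W_AIC)
#'
#' Sum of the Akaike weights of every model in which the predictor appears
#' (linear or unimodal).
#'
#' @param results A `model_set_result` from [run_model_set()].
#' @param predictor Predictor name.
#' @return W_AIC in `[0, 1]`.
#' @export
variable_importance <- function(results, predictor) {
  inc <- vapply(results$specs, function(s) s[[predictor]] > 0L, logical(1))
  sum(results$weights[inc])
}

#' Conditional model-averaged standardized coefficients
#'
#' For each term (linear `b` or quadratic `b2` of each predictor), the
#' weighted mean of its coefficient over the models containing it, weights
#' renormalized to those models (`sum w_i beta_i / sum w_i`). Terms whose
#' summed containing weight falls below `support_threshold` are reported but
#' flagged as low-support; terms absent from every model get `NA`.
#'
#' @param results A `model_set_result` from [run_model_set()].
#' @param support_threshold Flagging threshold on the containing weight sum.
#' @return `data.frame`: `predictor`, `term` (`"b"`/`"b2"`), `coefficient`,
#'   `weight_sum`, `low_support`.
#' @export
model_average_coefficients <- function(results, support_threshold = 0.01) {
  preds <- names(results$specs[[1]])
  rows <- list()
  for (pr in preds) {
    for (term in c("b", "b2")) {
      cname <- if (term == "b") pr else paste0(pr, "_sq")
      wsum <- 0; acc <- 0
      for (i in seq_along(results$specs)) {
        cf <- results$fits[[i]]$coefficients
        if (cname %in% names(cf)) {
          wsum <- wsum + results$weights[i]
          acc <- acc + results$weights[i] * cf[[cname]]
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        predictor = pr, term = term,
        coefficient = if (wsum > 0) acc / wsum else NA_real_,
        weight_sum = wsum,
        low_support = wsum < support_threshold,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Partial residuals of one term in a multi-predictor fit
#'
#' Computes `resid + b * x_term`, where `resid = y - X beta_hat` are the
#' trend residuals of the fitted model and `b` is the term's coefficient —
#' the quantity plotted to show a predictor's effect after all other
#' variables are statistically controlled.
#'
#' @param full_fit A [fit_sar_error()] result.
#' @param X The design matrix it was fitted with.
#' @param y The response.
#' @param term Column name of the term in `X`.
#' @return Numeric vector of partial residuals.
#' @export
partial_residuals <- function(full_fit, X, y, term) {
  X <- as.matrix(X)
  if (!term %in% colnames(X)) stop("term not in the design matrix")
  b <- full_fit$coefficients[[term]]
  r <- y - as.vector(X %*% full_fit$coefficients)
  r + b * X[, term]
}

# design matrix for one spec from the standardized predictor matrix
spec_design <- function(spec, Z) {
  X <- matrix(1, nrow(Z), 1L, dimnames = list(NULL, "(Intercept)"))
  for (pr in names(spec)) {
    if (spec[[pr]] >= 1L) X <- cbind(X, setNames2(Z[, pr], pr))
    if (spec[[pr]] == 2L) X <- cbind(X, setNames2(Z[, pr]^2, paste0(pr, "_sq")))
  }
  X
}

setNames2 <- function(v, nm) {
  m <- matrix(v, ncol = 1L, dimnames = list(NULL, nm))
  m
}

#' Fit an enumerated SAR-error model set
#'
#' Fits every specification on z-scored predictors (quadratic terms are
#' squares of the standardized predictor) and a z-scored response, then
#' computes Akaike weights over the set.
#'
#' @param Z Matrix of standardized predictor columns.
#' @param y Standardized response.
#' @param W A [build_weights()] object.
#' @param specs Model specifications from [enumerate_models()].
#' @return List of class `model_set_result`: `specs`, `fits`, `aic`,
#'   `weights`.
#' @export
run_model_set <- function(Z, y, W, specs) {
  fits <- vector("list", length(specs))
  for (i in seq_along(specs))
    fits[[i]] <- fit_sar_error(spec_design(specs[[i]], Z), y, W)
  aic <- vapply(fits, `[[`, numeric(1), "aic")
  structure(list(specs = specs, fits = fits, aic = aic,
                 weights = akaike_weights(aic)),
            class = "model_set_result")
}

#' Exhaustive multimodel inference over imputation replicates
#'
#' The full inference stage: configured skewed predictors are
#' log10-transformed, all predictors and the response are z-scored, the
#' exhaustive model set is fitted per imputation replicate, and per-predictor
#' relative support (W_AIC), single-predictor unimodal Nagelkerke pseudo-R2,
#' and conditional model-averaged coefficients are pooled (mean and 2.5/97.5
#' percentiles) across replicates.
#'
#' @param pred `data.frame` of predictor columns, one row per cell.
#' @param fd_values List of response vectors (one per imputation replicate),
#'   or a single vector.
#' @param W A [build_weights()] object.
#' @param predictors Predictor columns to use (default: all of `pred`).
#' @param log10_predictors Predictors to log10-transform first (values must
#'   be positive).
#' @param max_predictors Optional cap forwarded to [enumerate_models()].
#' @return List of class `inference_result`: `per_replicate` (list with
#'   `model_set`, `importance`, `pseudo_r2`, `coefficients`), `importance`,
#'   `pseudo_r2` and `coefficients` pooled `data.frame`s (mean, `lo`, `hi`),
#'   and `predictors`.
#' @export
run_inference <- function(pred, fd_values, W, predictors = names(pred),
                          log10_predictors = character(0),
                          max_predictors = NULL) {
  if (!is.list(fd_values)) fd_values <- list(fd_values)
  n <- nrow(pred)
  for (v in fd_values)
    if (length(v) != n) stop("cell sets of predictors and responses differ")
  Z <- as.matrix(pred[predictors])
  for (pr in intersect(log10_predictors, predictors)) {
    if (any(Z[, pr] <= 0)) stop("log10 predictor ", pr, " must be positive")
    Z[, pr] <- log10(Z[, pr])
  }
  Z <- scale(Z)
  specs <- enumerate_models(predictors, max_predictors)

  per_rep <- vector("list", length(fd_values))
  for (r in seq_along(fd_values)) {
    yz <- as.vector(scale(fd_values[[r]]))
    ms <- run_model_set(Z, yz, W, specs)
    imp <- vapply(predictors, function(pr) variable_importance(ms, pr),
                  numeric(1))
    null_fit <- fit_sar_error(matrix(1, n, 1L,
                                     dimnames = list(NULL, "(Intercept)")),
                              yz, W)
    pr2 <- vapply(predictors, function(pr) {
      spec <- setNames(rep(0L, length(predictors)), predictors)
      spec[pr] <- 2L
      nagelkerke_r2(fit_sar_error(spec_design(spec, Z), yz, W), null_fit)
    }, numeric(1))
    per_rep[[r]] <- list(model_set = ms, importance = imp, pseudo_r2 = pr2,
                         coefficients = model_average_coefficients(ms))
  }

  pool_vec <- function(get) {
    M <- do.call(cbind, lapply(per_rep, get))
    data.frame(mean = rowMeans(M),
               lo = apply(M, 1L, quantile, 0.025, na.rm = TRUE),
               hi = apply(M, 1L, quantile, 0.975, na.rm = TRUE))
  }
  importance <- cbind(data.frame(predictor = predictors),
                      pool_vec(function(x) x$importance))
  pseudo_r2 <- cbind(data.frame(predictor = predictors),
                     pool_vec(function(x) x$pseudo_r2))
  co <- per_rep[[1]]$coefficients[c("predictor", "term")]
  coefficients <- cbind(co, pool_vec(function(x) x$coefficients$coefficient))
  structure(list(per_replicate = per_rep, importance = importance,
                 pseudo_r2 = pseudo_r2, coefficients = coefficients,
                 predictors = predictors),
            class = "inference_result")
}

#' @export
print.inference_result <- function(x, ...) {
  cat("inference_result:", length(x$per_replicate), "replicate(s),",
      length(x$per_replicate[[1]]$model_set$specs), "models over",
      length(x$predictors), "predictors\n")
  cat("\nRelative support (W_AIC, pooled):\n")
  print(x$importance, row.names = FALSE, digits = 3)
  invisible(x)
}
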