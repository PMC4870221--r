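# Trait preparation: log10 transform + z-scoring, and a genus- and
# growth-form-constrained chained-equations imputation with predictive mean
# matching, repeated m times to propagate imputation uncertainty.

#' Log10-transform and standardize continuous traits
#'
#' Each continuous trait is log10-transformed and z-scored to mean 0, SD 1
#' over its observed entries (population SD, n denominator). The column
#' means/SDs are stored so the transform is exactly invertible.
#'
#' @param traits Trait table with positive continuous trait columns (`NA`
#'   allowed).
#' @param trait_cols Names of the continuous trait columns.
#' @return The table with transformed trait columns and an attribute
#'   `transform` (`data.frame` of per-trait log10 mean and SD).
#' @seealso [unstandardize_traits()]
#' @export
#' @examples
#' tt <- data.frame(species_id = c("a", "b", "c"), sla = c(1, 10, 100))
#' log_standardize(tt, "sla")$sla  # -1.2247, 0, 1.2247
log_standardize <- function(traits, trait_cols = .trait_names) {
  meta <- data.frame(trait = trait_cols, mean = NA_real_, sd = NA_real_)
  for (i in seq_along(trait_cols)) {
    tr <- trait_cols[i]
    v <- traits[[tr]]
    bad <- which(!is.na(v) & v <= 0)
    if (length(bad))
      stop("non-positive value of ", tr, " for species ",
           paste(traits$species_id[bad], collapse = ", "))
    lv <- log10(v)
    obs <- lv[!is.na(lv)]
    mu <- mean(obs)
    sdev <- sqrt(mean((obs - mu)^2))
    if (sdev == 0) stop("trait ", tr, " is constant (zero SD)")
    traits[[tr]] <- (lv - mu) / sdev
    meta$mean[i] <- mu
    meta$sd[i] <- sdev
  }
  attr(traits, "transform") <- meta
  traits
}

#' Invert [log_standardize()]
#'
#' @param traits Standardized table carrying the `transform` attribute (or
#'   pass `transform` explicitly).
#' @param transform The transform metadata `data.frame`.
#' @return The table back on natural units.
#' @export
unstandardize_traits <- function(traits, transform = attr(traits, "transform")) {
  if (is.null(transform)) stop("no transform metadata available")
  for (i in seq_len(nrow(transform))) {
    tr <- transform$trait[i]
    traits[[tr]] <- 10^(traits[[tr]] * transform$sd[i] + transform$mean[i])
  }
  attr(traits, "transform") <- NULL
  traits
}

# genus-mean covariate of one trait from originally observed values only;
# genera without observations fall back to growth-form means, then the
# overall mean -- static, hence leak-free across iterations
genus_mean_covariate <- function(y, genus, growth_form) {
  obs <- !is.na(y)
  gm <- tapply(y[obs], genus[obs], mean)
  fm <- tapply(y[obs], growth_form[obs], mean)
  out <- gm[genus]
  miss <- is.na(out)
  out[miss] <- fm[growth_form[miss]]
  out[is.na(out)] <- mean(y[obs])
  as.vector(out)
}

# least-squares fit dropping aliased columns; returns coefficient draw from
# the approximate posterior (Bayesian linear regression, flat prior)
draw_beta <- function(X, y) {
  qx <- qr(X)
  keep <- qx$pivot[seq_len(qx$rank)]
  Xk <- X[, keep, drop = FALSE]
  qk <- qr(Xk)
  bhat <- qr.coef(qk, y)
  res <- y - Xk %*% bhat
  df <- max(nrow(Xk) - ncol(Xk), 1L)
  sigma2 <- sum(res^2) / rchisq(1L, df)
  R <- qr.R(qk)
  z <- rnorm(ncol(Xk))
  bstar <- bhat + backsolve(R, z) * sqrt(sigma2)
  full <- numeric(ncol(X))
  full[keep] <- bstar
  full
}

#' Multiply-imputed trait tables via chained equations
#'
#' Fills trait gaps by iterated conditional regression on the standardized
#' log scale: each incomplete trait is regressed on the other three traits,
#' growth-form indicators, and a genus-mean covariate of the target trait
#' (the evolutionary constraint; computed from originally observed values,
#' with growth-form-mean fallback for genera lacking observations). Draws use
#' predictive mean matching with `k_pmm` donor candidates and per-iteration
#' Bayesian coefficient draws, so imputations always lie within the observed
#' support. `m` independent chains give `m` completed tables.
#'
#' @param traits Standardized trait table (output of [log_standardize()])
#'   with complete `genus` and `growth_form` columns.
#' @param m Number of imputed replicates (default 10).
#' @param max_iter Maximum chained-equation sweeps per chain.
#' @param seed Integer seed; chain `r` uses `seed + r - 1`.
#' @param trait_cols Continuous trait columns.
#' @param k_pmm Number of donor candidates for predictive mean matching.
#' @param tol Convergence tolerance: a chain stops when the mean absolute
#'   change of imputed values between sweeps falls below it.
#' @return List of class `imputed_set`: `replicates` (list of `m` complete
#'   tables), `m`, `seed`, and `convergence` (per-replicate vector of mean
#'   absolute changes per sweep).
#' @export
mice_impute <- function(traits, m = 10L, max_iter = 20L, seed = 1L,
                        trait_cols = .trait_names, k_pmm = 5L, tol = 1e-3) {
  if (m < 1L) stop("m must be at least 1")
  if (anyNA(traits$genus) || anyNA(traits$growth_form))
    stop("genus and growth_form must be complete")
  Z <- as.matrix(traits[trait_cols])
  n <- nrow(Z)
  n_obs <- colSums(!is.na(Z))
  if (any(n_obs < 10L))
    stop("traits with fewer than 10 observations: ",
         paste(trait_cols[n_obs < 10L], collapse = ", "))
  miss <- is.na(Z)
  incomplete <- trait_cols[colSums(miss) > 0L]

  gf <- factor(traits$growth_form)
  GF <- if (nlevels(gf) > 1L)
    model.matrix(~ gf)[, -1L, drop = FALSE] else NULL
  gmean <- sapply(trait_cols, function(tr)
    genus_mean_covariate(Z[, tr], traits$genus, traits$growth_form))

  replicates <- vector("list", m)
  convergence <- vector("list", m)
  for (r in seq_len(m)) {
    set.seed(as.integer(seed) + r - 1L)
    Zc <- Z
    for (tr in incomplete) {  # initialize from observed values
      mi <- miss[, tr]
      Zc[mi, tr] <- sample(Z[!mi, tr], sum(mi), replace = TRUE)
    }
    log_r <- numeric(0)
    if (length(incomplete)) {
      for (it in seq_len(max_iter)) {
        prev <- Zc[miss]
        for (tr in incomplete) {
          mi <- miss[, tr]
          others <- setdiff(trait_cols, tr)
          X <- cbind(1, Zc[, others, drop = FALSE], gmean[, tr])
          if (!is.null(GF)) X <- cbind(X, GF)
          b <- draw_beta(X[!mi, , drop = FALSE], Zc[!mi, tr])
          pred <- as.vector(X %*% b)
          po <- pred[!mi]; yo <- Zc[!mi, tr]
          pm <- pred[mi]
          k <- min(k_pmm, length(po))
          don <- vapply(pm, function(p) {
            cand <- order(abs(po - p))[seq_len(k)]
            yo[cand[sample.int(k, 1L)]]
          }, numeric(1))
          Zc[mi, tr] <- don
        }
        delta <- mean(abs(Zc[miss] - prev))
        log_r <- c(log_r, delta)
        if (delta < tol) break
      }
    }
    comp <- traits
    for (tr in trait_cols) comp[[tr]] <- Zc[, tr]
    replicates[[r]] <- comp
    convergence[[r]] <- log_r
  }
  structure(list(replicates = replicates, m = m, seed = as.integer(seed),
                 convergence = convergence, trait_cols = trait_cols),
            class = "imputed_set")
}

#' @export
print.imputed_set <- function(x, ...) {
  cat("imputed_set: m =", x$m, "replicates of", nrow(x$replicates[[1]]),
      "species; sweeps per chain:",
      paste(vapply(x$convergence, length, 1L), collapse = ", "), "\n")
  invisible(x)
}

#' Pool a quantity over imputation replicates
#'
#' Elementwise mean and min-max range across replicate vectors, the summary
#' used to report per-cell functional diversity over the `m` imputed trait
#' tables.
#'
#' @param values List of equal-length numeric vectors (one per replicate), or
#'   a matrix with one column per replicate.
#' @return `data.frame` with columns `mean`, `min`, `max`.
#' @export
pool_over_replicates <- function(values) {
  if (is.list(values)) {
    len <- unique(vapply(values, length, 1L))
    if (length(len) != 1L) stop("replicate vectors must share length")
    values <- do.call(cbind, values)
  }
  data.frame(mean = rowMeans(values),
             min = apply(values, 1L, min),
             max = apply(values, 1L, max))
}
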