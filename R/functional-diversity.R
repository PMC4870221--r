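# Per-cell functional diversity: convex-hull functional richness,
# functional dispersion, univariate trait range/SD, and richness-preserving
# null-model standardized effect sizes.

#' Functional richness: convex-hull volume in trait space
#'
#' Volume of the convex hull of the assemblage's species in standardized
#' trait space (units^d). Undefined (`NA`) when fewer than `d + 1` species
#' are present or the points are affinely degenerate; no perturbation
#' ("joggling") is applied, so degeneracy is reported rather than silently
#' resolved.
#'
#' @param trait_points Numeric n x d matrix, one row per species.
#' @param d Expected number of trait dimensions; an input with a different
#'   column count is an error.
#' @return Hull volume, or `NA_real_` when undefined.
#' @export
#' @examples
#' functional_richness(rbind(c(0,0,0), c(1,0,0), c(0,1,0), c(0,0,1)),
#'                     d = 3)  # 1/6
functional_richness <- function(trait_points, d = 4L) {
  trait_points <- as.matrix(trait_points)
  if (ncol(trait_points) != d)
    stop("expected ", d, " trait dimensions, got ", ncol(trait_points))
  if (nrow(trait_points) < d + 1L) return(NA_real_)
  .hull_volume_cpp(trait_points)
}

#' Functional dispersion: mean distance to the trait centroid
#'
#' Mean Euclidean distance of each species to the unweighted centroid of the
#' assemblage in standardized trait space; 0 for a single species or an
#' assemblage of identical trait vectors.
#'
#' @param trait_points Numeric n x d matrix.
#' @return Non-negative scalar.
#' @export
functional_dispersion <- function(trait_points) {
  trait_points <- as.matrix(trait_points)
  ctr <- colMeans(trait_points)
  mean(sqrt(rowSums(sweep(trait_points, 2L, ctr)^2)))
}

#' Univariate trait range and dispersion
#'
#' `(max - min, population SD)` of one trait across the assemblage; `(0, 0)`
#' for a single species. The population (n-denominator) SD is used: this is
#' a descriptive statistic of the assemblage, not an estimate.
#'
#' @param trait_values Numeric vector.
#' @return Named numeric `c(range, sd)`.
#' @export
univariate_range_sd <- function(trait_values) {
  mu <- mean(trait_values)
  c(range = max(trait_values) - min(trait_values),
    sd = sqrt(mean((trait_values - mu)^2)))
}

#' Richness-preserving randomization of an occurrence matrix
#'
#' For every cell, draws the same number of species uniformly without
#' replacement from the full species pool, so each row sum is preserved
#' exactly while species identities are randomized.
#'
#' @param occ An [occurrence_matrix()].
#' @param seed Integer seed.
#' @return A randomized [occurrence_matrix()].
#' @export
randomize_occurrence <- function(occ, seed) {
  set.seed(as.integer(seed))
  m <- occ$m
  ns <- ncol(m)
  rich <- rowSums(m)
  out <- matrix(0L, nrow(m), ns, dimnames = dimnames(m))
  for (i in seq_len(nrow(m)))
    out[i, sample.int(ns, rich[i])] <- 1L
  occurrence_matrix(out, occ$coords)
}

#' Standardized effect size against a null distribution
#'
#' `(observed - mean(null)) / sd(null)` with the sample (n-1) SD; `NA` with a
#' warning when the null SD is zero.
#'
#' @param observed Observed metric value.
#' @param null_values Numeric vector of null-model metric values (>= 2 finite
#'   values required).
#' @return SES, or `NA_real_` when undefined.
#' @export
ses <- function(observed, null_values) {
  nv <- null_values[is.finite(null_values)]
  if (length(nv) < 2L) stop("at least 2 finite null values required")
  s <- sd(nv)
  if (s == 0) {
    warning("zero null SD; SES undefined")
    return(NA_real_)
  }
  (observed - mean(nv)) / s
}

# metrics for all cells of one occurrence matrix given a trait matrix
cell_metrics <- function(m, Z, metrics, d) {
  ncell <- nrow(m)
  out <- list()
  if ("f_rich" %in% metrics) out$f_rich <- rep(NA_real_, ncell)
  if ("f_disp" %in% metrics) out$f_disp <- rep(NA_real_, ncell)
  for (i in seq_len(ncell)) {
    pts <- Z[m[i, ] == 1L, , drop = FALSE]
    if ("f_rich" %in% metrics)
      out$f_rich[i] <- if (nrow(pts) >= d + 1L) .hull_volume_cpp(pts) else NA_real_
    if ("f_disp" %in% metrics) out$f_disp[i] <- functional_dispersion(pts)
  }
  out
}

#' Per-cell functional diversity with null-model SES, over imputed replicates
#'
#' For each imputed trait table and each grid cell: species richness,
#' functional richness (hull volume), functional dispersion, univariate
#' range/SD per trait, and — when `n_null > 0` — standardized effect sizes
#' against `n_null` richness-preserving randomizations of the occurrence
#' matrix. Results are also pooled (mean and min-max range) across
#' replicates.
#'
#' @param occ An [occurrence_matrix()].
#' @param imputed An `imputed_set` ([mice_impute()]) or a single complete
#'   trait table on the standardized scale.
#' @param n_null Number of null randomizations (0 disables SES).
#' @param seed Integer seed for the null draws.
#' @param trait_cols Continuous trait columns.
#' @param null_metrics Metrics to compute under the null (SES can be
#'   restricted to `"f_disp"` to avoid hull computations across many
#'   randomizations).
#' @return List of class `fd_result`: `replicates` (list of per-cell
#'   `data.frame`s), `pooled` (`data.frame` of pooled mean/min/max of
#'   `f_rich`, `f_disp` and their SES), `n_null`, `seed`.
#' @export
fd_pipeline <- function(occ, imputed, n_null = 0L, seed = 1L,
                        trait_cols = .trait_names,
                        null_metrics = c("f_rich", "f_disp")) {
  reps <- if (inherits(imputed, "imputed_set")) imputed$replicates
  else list(imputed)
  d <- length(trait_cols)
  sp <- colnames(occ$m)
  ncell <- nrow(occ$m)
  rich <- rowSums(occ$m)

  res <- vector("list", length(reps))
  for (r in seq_along(res)) {
    tt <- reps[[r]]
    missing_sp <- setdiff(sp, tt$species_id)
    if (length(missing_sp))
      stop("species absent from traits: ",
           paste(head(missing_sp, 5L), collapse = ", "),
           if (length(missing_sp) > 5L) ", ...")
    if (anyNA(tt[trait_cols])) stop("trait table must be complete")
    Z <- as.matrix(tt[match(sp, tt$species_id), trait_cols, drop = FALSE])

    obs <- cell_metrics(occ$m, Z, c("f_rich", "f_disp"), d)
    df <- data.frame(cell = rownames(occ$m), richness = rich,
                     f_rich = obs$f_rich, f_disp = obs$f_disp,
                     stringsAsFactors = FALSE)
    for (tr in trait_cols) {
      rs <- t(apply(occ$m, 1L, function(row)
        univariate_range_sd(Z[row == 1L, tr])))
      df[[paste0("range_", tr)]] <- rs[, "range"]
      df[[paste0("sd_", tr)]] <- rs[, "sd"]
    }
    if (n_null > 0L) {
      acc <- list()
      for (mt in null_metrics)
        acc[[mt]] <- matrix(NA_real_, ncell, n_null)
      for (b in seq_len(n_null)) {
        rocc <- randomize_occurrence(occ, seed = seed + (r - 1L) * n_null + b)
        nm <- cell_metrics(rocc$m, Z, null_metrics, d)
        for (mt in null_metrics) acc[[mt]][, b] <- nm[[mt]]
      }
      for (mt in null_metrics) {
        obs_v <- df[[mt]]
        df[[paste0("ses_", mt)]] <- vapply(seq_len(ncell), function(i) {
          nv <- acc[[mt]][i, ]
          nv <- nv[is.finite(nv)]
          if (length(nv) < 2L || is.na(obs_v[i])) return(NA_real_)
          s <- sd(nv)
          if (s == 0) return(NA_real_)
          (obs_v[i] - mean(nv)) / s
        }, numeric(1))
      }
    }
    res[[r]] <- df
  }

  pool_cols <- intersect(c("f_rich", "f_disp", "ses_f_rich", "ses_f_disp"),
                         names(res[[1]]))
  pooled <- data.frame(cell = res[[1]]$cell, richness = rich)
  for (pc in pool_cols) {
    p <- pool_over_replicates(lapply(res, `[[`, pc))
    pooled[[paste0(pc, "_mean")]] <- p$mean
    pooled[[paste0(pc, "_min")]] <- p$min
    pooled[[paste0(pc, "_max")]] <- p$max
  }
  structure(list(replicates = res, pooled = pooled,
                 n_null = as.integer(n_null), seed = as.integer(seed)),
            class = "fd_result")
}

#' @export
print.fd_result <- function(x, ...) {
  cat("fd_result:", nrow(x$pooled), "cells x", length(x$replicates),
      "imputation replicate(s); n_null =", x$n_null, "\n")
  invisible(x)
}
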