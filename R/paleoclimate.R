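# Historical-predictor construction: multi-model ensemble averaging,
# change-factor downscaling of glacial anomalies, growing degree-days,
# glacial refugia masks, climate-change velocity, and inverse-distance
# accessibility to refugia.

#' Cellwise ensemble mean of climate grids
#'
#' Arithmetic mean across model grids, ignoring no-data; a cell is no-data in
#' the output only where every input is.
#'
#' @param grids List of [climate_grid()]s sharing georeference and variable.
#' @return A [climate_grid()].
#' @export
ensemble_mean <- function(grids) {
  if (!length(grids)) stop("at least one grid required")
  g1 <- grids[[1]]
  for (g in grids[-1]) {
    if (!same_georef(g1, g)) stop("ensemble members must share georeference")
    if (!identical(g1$variable, g$variable))
      stop("ensemble members must share the variable tag")
  }
  tot <- array(0, dim(g1$values))
  cnt <- array(0L, dim(g1$values))
  for (g in grids) {
    ok <- !is.na(g$values)
    tot[ok] <- tot[ok] + g$values[ok]
    cnt <- cnt + ok
  }
  out <- tot / cnt
  out[cnt == 0L] <- NA_real_
  climate_grid(out, g1$cell_size_km, g1$xll, g1$yll, g1$variable, g1$epoch)
}

#' Change-factor downscaling of a coarse glacial surface
#'
#' Applies the coarse-model glacial anomaly to a fine-resolution present-day
#' baseline: additive for temperature (`fine_lgm = fine_present +
#' interp(coarse_lgm - coarse_present)`), multiplicative for precipitation
#' (`fine_lgm = fine_present * interp(coarse_lgm / max(coarse_present,
#' eps))`, clipped at 0). Anomalies are interpolated bilinearly between
#' coarse cell centres, with constant extrapolation at the margins, so a
#' spatially constant change factor is reproduced exactly.
#'
#' @param coarse_lgm,coarse_present Coarse [climate_grid()]s sharing
#'   georeference and variable.
#' @param fine_present Fine-resolution present-day baseline of the same
#'   variable, nested within the coarse extent.
#' @param eps Precipitation denominator floor (mm), guarding dry cells.
#' @return Fine-resolution glacial [climate_grid()].
#' @export
change_factor_downscale <- function(coarse_lgm, coarse_present, fine_present,
                                    eps = 0.1) {
  if (!same_georef(coarse_lgm, coarse_present))
    stop("coarse grids must share georeference")
  if (!identical(coarse_lgm$variable, coarse_present$variable) ||
      !identical(coarse_lgm$variable, fine_present$variable))
    stop("variable tags must match across all three grids")
  variable <- fine_present$variable
  if (is.null(variable)) stop("grids must carry a variable tag")

  anom <- if (variable == "precipitation")
    coarse_lgm$values / pmax(coarse_present$values, eps)
  else coarse_lgm$values - coarse_present$values

  # coarse cell-centre axes, increasing x and y (flip rows: row 1 is north)
  nrc <- nrow(anom); ncc <- ncol(anom); cs <- coarse_lgm$cell_size_km
  xs <- coarse_lgm$xll + (seq_len(ncc) - 0.5) * cs
  ys <- coarse_lgm$yll + (seq_len(nrc) - 0.5) * cs
  Z <- anom[rev(seq_len(nrc)), , drop = FALSE]  # row 1 now southernmost

  fc <- grid_coords(fine_present)
  xp <- pmin(pmax(fc$x, xs[1]), xs[length(xs)])
  yp <- pmin(pmax(fc$y, ys[1]), ys[length(ys)])
  a <- pracma::interp2(xs, ys, Z, xp, yp, method = "linear")
  A <- matrix(a, nrow(fine_present$values), ncol(fine_present$values),
              byrow = TRUE)

  vals <- if (variable == "precipitation")
    pmax(fine_present$values * A, 0)
  else fine_present$values + A
  climate_grid(vals, fine_present$cell_size_km, fine_present$xll,
               fine_present$yll, variable, epoch = "lgm")
}

.days_in_month <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)

#' Growing degree-days from monthly mean temperatures
#'
#' `sum over months of max(0, T_m - base) * days_in_month` on a 365-day
#' (non-leap) calendar; degree C * day.
#'
#' @param monthly_temps List of 12 monthly mean-temperature
#'   [climate_grid()]s.
#' @param base Base temperature, degrees C.
#' @return A [climate_grid()] of GDD.
#' @export
growing_degree_days <- function(monthly_temps, base = 5) {
  if (length(monthly_temps) != 12L) stop("12 monthly grids required")
  g1 <- monthly_temps[[1]]
  acc <- array(0, dim(g1$values))
  for (m in 1:12) {
    g <- monthly_temps[[m]]
    if (!same_georef(g1, g)) stop("monthly grids must share georeference")
    acc <- acc + pmax(g$values - base, 0) * .days_in_month[m]
  }
  climate_grid(acc, g1$cell_size_km, g1$xll, g1$yll, "gdd", g1$epoch)
}

#' Glacial refugia mask
#'
#' A cell is refugial iff all three threshold conditions hold, boundary
#' values inclusive: growing degree-days, mean temperature of the coldest
#' month, and summer (June-August) precipitation. The default coldest-month
#' threshold is -15 degrees C, a minimum cold-tolerance bound for
#' cool-temperate trees (see the methods vignette for the discussion of this
#' choice); all thresholds are configurable.
#'
#' @param gdd,tcold,psummer [climate_grid()]s sharing georeference: growing
#'   degree-days (degree C * day), coldest-month mean temperature (degrees
#'   C), and summer precipitation total (mm).
#' @param thresholds List with `gdd_min`, `tcold_min`, `psummer_min`.
#' @return List of class `refugia_mask`: logical matrix `mask` (NA where any
#'   input is no-data), the thresholds used, and the georeference.
#' @export
refugia_mask <- function(gdd, tcold, psummer,
                         thresholds = list(gdd_min = 800, tcold_min = -15,
                                           psummer_min = 50)) {
  if (!same_georef(gdd, tcold) || !same_georef(gdd, psummer))
    stop("refugia inputs must share georeference")
  m <- gdd$values >= thresholds$gdd_min &
    tcold$values >= thresholds$tcold_min &
    psummer$values >= thresholds$psummer_min
  structure(list(mask = m, thresholds = thresholds,
                 cell_size_km = gdd$cell_size_km,
                 xll = gdd$xll, yll = gdd$yll),
            class = "refugia_mask")
}

#' @export
print.refugia_mask <- function(x, ...) {
  cat("refugia_mask:", sum(x$mask, na.rm = TRUE), "of", length(x$mask),
      "cells refugial (gdd >=", x$thresholds$gdd_min, ", tcold >=",
      x$thresholds$tcold_min, ", psummer >=", x$thresholds$psummer_min, ")\n")
  invisible(x)
}

# Horn's 3x3 slope magnitude, units per km; edge cells use available
# neighbours via edge replication
horn_gradient <- function(z, cell_size_km) {
  nr <- nrow(z); nc <- ncol(z)
  zp <- z[c(1, seq_len(nr), nr), c(1, seq_len(nc), nc)]  # replicate-pad
  i <- 1 + seq_len(nr); j <- 1 + seq_len(nc)
  gx <- ((zp[i - 1, j + 1] + 2 * zp[i, j + 1] + zp[i + 1, j + 1]) -
           (zp[i - 1, j - 1] + 2 * zp[i, j - 1] + zp[i + 1, j - 1])) /
    (8 * cell_size_km)
  # row index grows southward, so the north-south derivative is negated;
  # only the magnitude is used
  gy <- ((zp[i + 1, j - 1] + 2 * zp[i + 1, j] + zp[i + 1, j + 1]) -
           (zp[i - 1, j - 1] + 2 * zp[i - 1, j] + zp[i - 1, j + 1])) /
    (8 * cell_size_km)
  sqrt(gx^2 + gy^2)
}

#' Climate-change velocity between two epochs
#'
#' Ratio of the temporal trend (absolute glacial-to-present anomaly per
#' decade) to the local spatial gradient of the present-day surface,
#' estimated as Horn's slope magnitude over the 3x3 neighbourhood. Gradients
#' are floored at `g_min` to keep velocities bounded on flat terrain; floored
#' cells are flagged.
#'
#' @param present,lgm [climate_grid()]s of one variable, shared georeference.
#' @param years Elapsed time between the epochs (default 21,000 years since
#'   the Last Glacial Maximum).
#' @param g_min Gradient floor, units per km.
#' @return List of class `velocity_grid`: `velocity` and `log10_velocity`
#'   [climate_grid()]s (km per decade; log10 only where positive), the
#'   `gradient` grid, and a logical `floored` matrix.
#' @export
climate_velocity <- function(present, lgm, years = 21000, g_min = 1e-5) {
  if (years <= 0) stop("years must be positive")
  if (!same_georef(present, lgm)) stop("epoch grids must share georeference")
  trend <- abs(present$values - lgm$values) / (years / 10)  # units/decade
  grad <- horn_gradient(present$values, present$cell_size_km)
  floored <- grad < g_min & !is.na(grad)
  v <- trend / pmax(grad, g_min)
  lv <- ifelse(!is.na(v) & v > 0, log10(v), NA_real_)
  mk <- function(x, var) climate_grid(x, present$cell_size_km, present$xll,
                                      present$yll, var, NULL)
  structure(list(velocity = mk(v, paste0(present$variable, "_velocity")),
                 log10_velocity = mk(lv, paste0("log10_", present$variable,
                                                "_velocity")),
                 gradient = mk(grad, paste0(present$variable, "_gradient")),
                 floored = floored),
            class = "velocity_grid")
}

#' Accessibility to glacial refugia
#'
#' For each focal cell, the sum of inverse Euclidean centroid distances (km)
#' to every refugial cell; a refugial focal cell contributes a self-term with
#' distance `cell_size_km / 2`.
#'
#' @param coords `data.frame` with `x`, `y` centroids (km) of the focal
#'   cells, in the row-major cell order.
#' @param refugia A [refugia_mask()] on the same grid, or a list with
#'   elements `coords` (`data.frame` of refugial centroids) and
#'   `cell_size_km`.
#' @return Numeric vector (1/km), one value per focal cell.
#' @export
accessibility <- function(coords, refugia) {
  if (inherits(refugia, "refugia_mask")) {
    g <- climate_grid(refugia$mask * 1, refugia$cell_size_km,
                      refugia$xll, refugia$yll)
    rc <- grid_coords(g)[which(as.vector(t(refugia$mask))), , drop = FALSE]
    cs <- refugia$cell_size_km
  } else {
    rc <- refugia$coords
    cs <- refugia$cell_size_km
  }
  n <- nrow(coords)
  if (nrow(rc) == 0L) {
    warning("no refugial cells; accessibility is zero everywhere")
    return(rep(0, n))
  }
  d <- sqrt(outer(coords$x, rc$x, "-")^2 + outer(coords$y, rc$y, "-")^2)
  d[d < 1e-9] <- cs / 2  # focal cell is itself refugial
  rowSums(1 / d)
}
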