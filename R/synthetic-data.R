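# Synthetic study system: correlated lognormal traits with genus structure,
# atlas-style occurrences along an environmental richness gradient, paired
# present/glacial climate surfaces, and SAR-error responses with known
# parameters.

# log10-scale location/scale of each trait; units cm2/g, mg, m, kg/m3
.trait_log10_mean <- c(sla = 2.2, seed_mass = 0.3, max_height = -0.2,
                       stem_density = 2.6)
.trait_log10_sd <- c(sla = 0.3, seed_mass = 1.0, max_height = 0.6,
                     stem_density = 0.15)
# growth-form offsets on log10 maximum height only, so the marginal
# inter-trait correlations stay at trait_corr
.gf_height_offset <- c(fern = -0.2, graminoid = -0.1, forb = -0.2,
                       shrub = 0.3, tree = 0.9, climber = 0.2)
.gf_prob <- c(fern = 0.05, graminoid = 0.20, forb = 0.45,
              shrub = 0.15, tree = 0.10, climber = 0.05)
# genus-level share of total log-scale trait variance
.genus_var_share <- 0.15

#' Generate a complete species-by-trait table
#'
#' Draws four continuous traits (specific leaf area, seed mass, maximum stem
#' height, stem/wood density) lognormally on the log10 scale with the
#' configured inter-trait correlation, decomposed into genus-level random
#' intercepts (15% of variance, same correlation structure) and species-level
#' deviations, so the marginal log-scale correlation equals `cfg$trait_corr`.
#' Growth form is assigned per genus and shifts log10 maximum height only.
#'
#' @param cfg A [synthetic_config()].
#' @return A `data.frame` with columns `species_id`, `genus`, `growth_form`
#'   and the four traits in natural units (no missing values).
#' @export
#' @examples
#' tr <- generate_traits(synthetic_config(n_species = 50, n_genera = 10,
#'                                        seed = 1))
#' summary(tr$sla)
generate_traits <- function(cfg) {
  validate_synthetic_config(cfg)
  set.seed(cfg$seed)
  n <- cfg$n_species
  ng <- cfg$n_genera
  # every genus appears at least once
  genus_idx <- c(seq_len(ng), sample.int(ng, n - ng, replace = TRUE))
  genus_idx <- sample(genus_idx)  # shuffle so genus order is not positional
  genus <- sprintf("G%03d", genus_idx)
  gf_by_genus <- sample(.growth_forms, ng, replace = TRUE, prob = .gf_prob)
  growth_form <- gf_by_genus[genus_idx]

  L <- chol(cfg$trait_corr)
  g2 <- .genus_var_share
  genus_eff <- (matrix(rnorm(ng * 4), ng, 4) %*% L) * sqrt(g2)
  sp_eff <- (matrix(rnorm(n * 4), n, 4) %*% L) * sqrt(1 - g2)
  z <- genus_eff[genus_idx, , drop = FALSE] + sp_eff
  logt <- sweep(sweep(z, 2, .trait_log10_sd, "*"), 2, .trait_log10_mean, "+")
  colnames(logt) <- .trait_names
  logt[, "max_height"] <- logt[, "max_height"] + .gf_height_offset[growth_form]

  out <- data.frame(species_id = sprintf("sp%04d", seq_len(n)),
                    genus = genus, growth_form = growth_form,
                    stringsAsFactors = FALSE)
  for (tr in .trait_names) out[[tr]] <- 10^logt[, tr]
  out
}

#' Mask trait values completely at random
#'
#' Applies a missing-completely-at-random mask per trait at the requested
#' rate; the number of masked cells per column is `round(n * rate)` exactly.
#' `genus` and `growth_form` are never masked.
#'
#' @param traits A trait table as returned by [generate_traits()].
#' @param rates Named vector of fractions in `[0, 1)`; names must be trait
#'   columns of `traits`.
#' @param seed Integer seed.
#' @return The table with `NA`s injected.
#' @export
inject_missingness <- function(traits, rates, seed) {
  if (any(rates >= 1) || any(rates < 0))
    stop("missingness rates must lie in [0, 1)")
  bad <- setdiff(names(rates), names(traits))
  if (length(bad)) stop("unknown trait columns: ", paste(bad, collapse = ", "))
  set.seed(as.integer(seed))
  n <- nrow(traits)
  for (tr in names(rates)) {
    n_miss <- round(n * rates[[tr]])
    if (n_miss > 0) traits[[tr]][sample.int(n, n_miss)] <- NA_real_
  }
  traits
}

#' Grid-cell by species occurrence matrix
#'
#' Light container for a binary cells-by-species matrix on a projected
#' equal-area grid: the matrix plus one centroid coordinate pair (km) per
#' cell.
#'
#' @param m Binary matrix with cell and species dimnames.
#' @param coords `data.frame` with numeric columns `x`, `y` (km), one row per
#'   cell of `m`.
#' @return An object of class `occurrence_matrix`.
#' @export
occurrence_matrix <- function(m, coords) {
  m <- as.matrix(m)
  if (!all(m %in% c(0, 1))) stop("occurrence entries must be 0/1")
  if (nrow(coords) != nrow(m)) stop("one coordinate row per cell required")
  if (!all(c("x", "y") %in% names(coords))) stop("coords needs columns x, y")
  if (any(rowSums(m) < 1)) stop("every retained cell must have richness >= 1")
  if (is.null(rownames(m))) rownames(m) <- sprintf("cell%04d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("sp%04d", seq_len(ncol(m)))
  structure(list(m = m, coords = as.data.frame(coords)[c("x", "y")]),
            class = "occurrence_matrix")
}

#' @export
print.occurrence_matrix <- function(x, ...) {
  cat("occurrence_matrix:", nrow(x$m), "cells x", ncol(x$m), "species;",
      "richness", min(rowSums(x$m)), "-", max(rowSums(x$m)), "\n")
  invisible(x)
}

#' Generate occurrences along an environmental richness gradient
#'
#' Per-cell richness is a deterministic monotone (linear) rescaling of a
#' designated environmental column into `cfg$richness_range`. Species are
#' then drawn without replacement with Gaussian inclusion weights centred on
#' a trait optimum, with kernel width shrinking where the designated
#' filtering predictor is extreme, so trait space (and hence hull volume)
#' narrows in strongly filtered cells.
#'
#' @param cfg A [synthetic_config()].
#' @param env `data.frame` with one row per grid cell (row-major, row 1 =
#'   north) containing the driver columns.
#' @param traits Complete trait table for the species pool
#'   ([generate_traits()]); filtering acts on standardized log10 maximum
#'   height.
#' @param richness_col Column of `env` that sets the richness gradient.
#' @param filter_col Column of `env` whose absolute (standardized) value
#'   narrows the trait filter.
#' @param filter_strength Non-negative; 0 disables trait filtering.
#' @return An [occurrence_matrix()] with cell centroids in km.
#' @export
generate_occurrences <- function(cfg, env, traits,
                                 richness_col = "accessibility",
                                 filter_col = "gdd",
                                 filter_strength = 1) {
  validate_synthetic_config(cfg)
  ncell <- cfg$grid_nrows * cfg$grid_ncols
  if (nrow(env) != ncell)
    stop("env must have one row per grid cell (", ncell, ")")
  if (cfg$richness_range[2] > cfg$n_species)
    stop("richness_range maximum exceeds the species pool")
  if (nrow(traits) != cfg$n_species)
    stop("traits must cover the configured species pool")
  set.seed(cfg$seed + 1L)

  v <- env[[richness_col]]
  s <- if (diff(range(v)) > 0) (v - min(v)) / diff(range(v)) else rep(0.5, ncell)
  rich <- as.integer(round(cfg$richness_range[1] +
                             s * diff(cfg$richness_range)))

  tz <- as.vector(scale(log10(traits$max_height)))
  f <- abs(as.vector(scale(env[[filter_col]])))  # 0 = no filtering

  m <- matrix(0L, ncell, cfg$n_species,
              dimnames = list(sprintf("cell%04d", seq_len(ncell)),
                              traits$species_id))
  for (i in seq_len(ncell)) {
    w <- exp(-0.5 * filter_strength * f[i] * tz^2) + 1e-12
    m[i, sample.int(cfg$n_species, rich[i], prob = w)] <- 1L
  }
  occurrence_matrix(m, grid_cell_coords(cfg))
}

#' Centroid coordinates of the configured grid
#'
#' Row-major ordering, row 1 northernmost; projected km with the origin at
#' the grid's southwest corner.
#'
#' @param cfg A [synthetic_config()].
#' @return `data.frame` with columns `x`, `y` in km.
#' @export
grid_cell_coords <- function(cfg) {
  cs <- cfg$cell_size_km
  rows <- rep(seq_len(cfg$grid_nrows), each = cfg$grid_ncols)
  cols <- rep(seq_len(cfg$grid_ncols), times = cfg$grid_nrows)
  data.frame(x = (cols - 0.5) * cs,
             y = (cfg$grid_nrows - rows + 0.5) * cs)
}

# standardized smooth pseudo-random surface: a seeded sum of low-frequency
# sinusoids, used as topography-like texture in the climate generators
smooth_surface <- function(nr, nc, seed, nterms = 4L) {
  set.seed(as.integer(seed))
  latfrac <- (nr - row(matrix(0, nr, nc))) / max(nr - 1, 1)
  colfrac <- (col(matrix(0, nr, nc)) - 1) / max(nc - 1, 1)
  s <- matrix(0, nr, nc)
  for (k in seq_len(nterms)) {
    fx <- runif(1, 0.5, 2.5); fy <- runif(1, 0.5, 2.5)
    ph <- runif(2, 0, 2 * pi)
    s <- s + (1 / k) * sin(2 * pi * fx * colfrac + ph[1]) *
      cos(2 * pi * fy * latfrac + ph[2])
  }
  (s - mean(s)) / sd(as.vector(s))
}

#' Generate paired present and glacial climate surfaces
#'
#' Present-day monthly temperature combines a smooth latitudinal gradient, a
#' seeded topography-like texture surface, and a sinusoidal seasonal cycle
#' whose amplitude grows eastward (continentality); precipitation is positive
#' with its own longitudinal gradient and texture. The glacial surface
#' subtracts a temperature anomaly that grows towards the grid's northern
#' edge with its own spatial texture, and scales precipitation by a spatially
#' varying ratio. The distinct textures keep the derived predictors (growing
#' degree-days, coldest-month temperature, velocities, accessibility) only
#' weakly correlated, emulating an atlas-scale predictor set without strong
#' multicollinearity.
#'
#' @param cfg A [synthetic_config()].
#' @param temp_anomaly `c(south, north)` glacial cooling in degrees C at the
#'   southern and northern grid edges (subtracted from the present surface).
#' @param prec_ratio Mean glacial/present precipitation ratio (> 0).
#' @param texture Amplitude of the spatial texture in the anomaly fields
#'   (degrees C; 0 gives an exactly latitudinal temperature anomaly and a
#'   spatially constant precipitation ratio).
#' @return Nested list `list(present, lgm)`, each holding `temperature` and
#'   `precipitation` as lists of 12 monthly [climate_grid()]s.
#' @export
generate_climate_pair <- function(cfg, temp_anomaly = c(6, 12),
                                  prec_ratio = 0.7, texture = 1.5) {
  validate_synthetic_config(cfg)
  nr <- cfg$grid_nrows; nc <- cfg$grid_ncols; cs <- cfg$cell_size_km
  # fraction of the way towards the northern (top) row
  latfrac <- (nr - row(matrix(0, nr, nc))) / max(nr - 1, 1)
  colfrac <- (col(matrix(0, nr, nc)) - 1) / max(nc - 1, 1)
  topo <- smooth_surface(nr, nc, cfg$seed + 101L)
  ptopo <- smooth_surface(nr, nc, cfg$seed + 102L)
  atopo <- smooth_surface(nr, nc, cfg$seed + 103L)
  rtopo <- smooth_surface(nr, nc, cfg$seed + 104L)
  wtopo <- smooth_surface(nr, nc, cfg$seed + 105L)  # winter-only texture
  stopo <- smooth_surface(nr, nc, cfg$seed + 106L)  # summer-only texture

  anom <- temp_anomaly[1] + (temp_anomaly[2] - temp_anomaly[1]) * latfrac +
    texture * atopo
  ratio <- pmin(pmax(prec_ratio * (1 + 0.15 * texture * rtopo), 0.2), 1.2)
  amp <- 6 + 8 * colfrac + 0.5 * topo  # continental (eastern) seasonality

  mk <- function(values, variable, epoch)
    climate_grid(values, cell_size_km = cs, variable = variable, epoch = epoch)
  pres <- list(temperature = vector("list", 12L),
               precipitation = vector("list", 12L))
  lgm <- pres
  for (m in 1:12) {
    seas <- cos(2 * pi * (m - 7) / 12)
    tp <- 15 - 12 * latfrac + 3 * topo + amp * seas +
      2 * wtopo * pmax(-seas, 0) + 2 * stopo * pmax(seas, 0)
    pp <- pmax(55 + 25 * colfrac - 10 * latfrac + 20 * ptopo + 15 * seas, 5)
    pres$temperature[[m]] <- mk(tp, "temperature", "present")
    pres$precipitation[[m]] <- mk(pp, "precipitation", "present")
    lgm$temperature[[m]] <- mk(tp - anom, "temperature", "lgm")
    lgm$precipitation[[m]] <- mk(pp * ratio, "precipitation", "lgm")
  }
  list(present = pres, lgm = lgm)
}

#' Simulate a response through the SAR-error process
#'
#' Draws `y = X beta + u` with spatially autocorrelated errors
#' `u = lambda W u + eps`, `eps ~ N(0, noise_sd^2 I)`; `u` is obtained by
#' solving `(I - lambda W) u = eps` exactly. Effects apply to z-scored
#' predictor columns, matching the standardized-coefficient convention of the
#' fitting pipeline.
#'
#' @param pred `data.frame` of predictor columns, one row per cell.
#' @param effects Named numeric vector; names must be columns of `pred`.
#' @param sar_lambda Autoregressive parameter in (-1, 1).
#' @param W A [build_weights()] object (row-standardized).
#' @param noise_sd Innovation SD (>= 0).
#' @param seed Integer seed.
#' @return Numeric response vector with attributes `u` and `eps` (the exact
#'   simulated error components).
#' @export
generate_response <- function(pred, effects, sar_lambda, W, noise_sd, seed) {
  if (abs(sar_lambda) >= 1) stop("sar_lambda must lie in (-1, 1)")
  bad <- setdiff(names(effects), names(pred))
  if (length(bad)) stop("effects name unknown predictors: ",
                        paste(bad, collapse = ", "))
  n <- nrow(pred)
  if (W$n != n) stop("weights dimension does not match pred")
  set.seed(as.integer(seed))
  X <- scale(as.matrix(pred[names(effects)]))
  eps <- rnorm(n, 0, noise_sd)
  A <- Matrix::Diagonal(n) - sar_lambda * W$W
  u <- as.vector(Matrix::solve(A, eps))
  y <- as.vector(X %*% effects) + u
  attr(y, "u") <- u
  attr(y, "eps") <- eps
  y
}
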