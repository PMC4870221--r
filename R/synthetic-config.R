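#' Configuration for the synthetic-data generators
#'
#' Bundles every knob of the synthetic study system: a rectangular equal-area
#' grid, a species pool with genus/growth-form structure and correlated
#' lognormal traits, atlas-style missingness rates, an environmental richness
#' gradient, and the spatial autoregressive data-generating process used for
#' recovery experiments. Defaults describe the study conditions the package's
#' validation suite runs under (see the methods vignette).
#'
#' @param grid_nrows,grid_ncols Grid dimensions (each >= 3). Row 1 is the
#'   northernmost row.
#' @param cell_size_km Cell edge length in km (> 0); cells are equal-area.
#' @param n_species Size of the species pool (>= 2 * `n_genera`).
#' @param n_genera Number of genera species are nested in.
#' @param trait_corr 4x4 symmetric positive-definite correlation matrix of the
#'   log10-scale traits, in the order `sla`, `seed_mass`, `max_height`,
#'   `stem_density`.
#' @param missing_rates Named fractions in `[0, 1)` of species to mask per
#'   trait. Defaults are the gap proportions typical of compiled European
#'   trait databases (SLA 50%, maximum height 53%, seed mass 50%, stem/wood
#'   density 42%).
#' @param richness_range Integer `c(min, max)` per-cell species richness;
#'   `min >= 1`, `max <= n_species`.
#' @param sar_lambda Spatial autoregressive error parameter in (-1, 1) of the
#'   simulated response process.
#' @param effect_sizes Named numeric vector of standardized effects used by
#'   [generate_response()]; names must be predictor columns.
#' @param noise_sd Innovation SD of the simulated response process.
#' @param seed Integer base seed; every generator is deterministic given it.
#'
#' @return A validated list of class `synthetic_config`.
#' @seealso [generate_traits()], [generate_occurrences()],
#'   [generate_climate_pair()], [generate_response()]
#' @export
#' @examples
#' cfg <- synthetic_config(grid_nrows = 5, grid_ncols = 5, n_species = 40,
#'                         n_genera = 10, seed = 1)
#' str(cfg$trait_corr)
synthetic_config <- function(grid_nrows = 20, grid_ncols = 20,
                             cell_size_km = 50,
                             n_species = 300, n_genera = 60,
                             trait_corr = default_trait_corr(),
                             missing_rates = c(sla = 0.50, seed_mass = 0.50,
                                               max_height = 0.53,
                                               stem_density = 0.42),
                             richness_range = c(10L, 60L),
                             sar_lambda = 0.5,
                             effect_sizes = c(accessibility = 0.6, gdd = 0.4),
                             noise_sd = 1,
                             seed = 42L) {
  cfg <- list(grid_nrows = as.integer(grid_nrows),
              grid_ncols = as.integer(grid_ncols),
              cell_size_km = cell_size_km,
              n_species = as.integer(n_species),
              n_genera = as.integer(n_genera),
              trait_corr = trait_corr,
              missing_rates = missing_rates,
              richness_range = as.integer(richness_range),
              sar_lambda = sar_lambda,
              effect_sizes = effect_sizes,
              noise_sd = noise_sd,
              seed = as.integer(seed))
  class(cfg) <- "synthetic_config"
  validate_synthetic_config(cfg)
  cfg
}

#' Default log-scale trait correlation matrix
#'
#' Modest allometric structure typical of herbaceous-dominated floras: seed
#' mass and maximum height positively related, specific leaf area negatively
#' related to stem density.
#'
#' @return A 4x4 positive-definite correlation matrix.
#' @export
default_trait_corr <- function() {
  nm <- .trait_names
  R <- diag(4)
  dimnames(R) <- list(nm, nm)
  R["sla", "seed_mass"] <- R["seed_mass", "sla"] <- -0.2
  R["sla", "max_height"] <- R["max_height", "sla"] <- -0.1
  R["sla", "stem_density"] <- R["stem_density", "sla"] <- -0.3
  R["seed_mass", "max_height"] <- R["max_height", "seed_mass"] <- 0.5
  R["seed_mass", "stem_density"] <- R["stem_density", "seed_mass"] <- 0.1
  R["max_height", "stem_density"] <- R["stem_density", "max_height"] <- 0.3
  R
}

.trait_names <- c("sla", "seed_mass", "max_height", "stem_density")
.growth_forms <- c("fern", "graminoid", "forb", "shrub", "tree", "climber")

validate_synthetic_config <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (cfg$grid_nrows < 3L || cfg$grid_ncols < 3L)
    stop("grid dimensions must be at least 3 x 3")
  if (cfg$cell_size_km <= 0) stop("cell_size_km must be positive")
  if (cfg$n_species < 2L * cfg$n_genera)
    stop("n_species must be at least twice n_genera")
  R <- cfg$trait_corr
  if (!is.matrix(R) || any(dim(R) != 4L))
    stop("trait_corr must be a 4 x 4 matrix")
  if (max(abs(R - t(R))) > 1e-10)
    stop("trait_corr must be symmetric")
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10)
    stop("trait_corr must be positive-definite")
  if (any(cfg$missing_rates < 0) || any(cfg$missing_rates >= 1))
    stop("missing_rates must lie in [0, 1)")
  rr <- cfg$richness_range
  if (length(rr) != 2L || rr[1] < 1L || rr[2] < rr[1])
    stop("richness_range must be c(min, max) with min >= 1")
  if (abs(cfg$sar_lambda) >= 1) stop("sar_lambda must lie in (-1, 1)")
  if (cfg$noise_sd < 0) stop("noise_sd must be non-negative")
  invisible(cfg)
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("synthetic_config:", x$grid_nrows, "x", x$grid_ncols, "grid (",
      x$cell_size_km, "km cells ),", x$n_species, "species in",
      x$n_genera, "genera; richness", x$richness_range[1], "-",
      x$richness_range[2], "; lambda =", x$sar_lambda,
      "; seed =", x$seed, "\n")
  invisible(x)
}
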