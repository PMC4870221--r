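# Small fixture builders shared across test files. Everything is generated
# in code; sizes are kept small so the default test run stays fast.

small_cfg <- function(seed = 7, ...) {
  args <- list(grid_nrows = 8, grid_ncols = 8, n_species = 80, n_genera = 16,
               richness_range = c(6L, 25L), seed = seed)
  args[names(list(...))] <- list(...)
  do.call(synthetic_config, args)
}

# correlation matrix with constant off-diagonal
corr_mat <- function(rho) {
  R <- matrix(rho, 4, 4)
  diag(R) <- 1
  nm <- c("sla", "seed_mass", "max_height", "stem_density")
  dimnames(R) <- list(nm, nm)
  R
}

trait_cols <- c("sla", "seed_mass", "max_height", "stem_density")

# an arbitrary small occurrence matrix over a given species pool
random_occurrence <- function(ncell, pool, rich_range = c(5L, 15L), seed = 1) {
  set.seed(seed)
  rich <- sample(rich_range[1]:rich_range[2], ncell, replace = TRUE)
  m <- matrix(0L, ncell, length(pool),
              dimnames = list(sprintf("c%03d", seq_len(ncell)), pool))
  for (i in seq_len(ncell)) m[i, sample.int(length(pool), rich[i])] <- 1L
  occurrence_matrix(m, data.frame(x = runif(ncell, 0, 500),
                                  y = runif(ncell, 0, 500)))
}

# constant-valued climate grid
const_grid <- function(value, nr = 5, nc = 5, cs = 50, variable = NULL,
                       epoch = NULL) {
  climate_grid(matrix(value, nr, nc), cell_size_km = cs, variable = variable,
               epoch = epoch)
}
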