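# End-to-end orchestration: synthetic inputs -> imputation -> functional
# diversity (+SES) -> historical/contemporary predictors -> exhaustive
# SAR-error multimodel inference, with every stage written to disk and all
# seeds logged in a manifest.

#' Build the per-cell predictor table from paired climate surfaces
#'
#' Derives the historical predictors (accessibility to glacial refugia,
#' temperature and precipitation velocity) and a contemporary set (growing
#' degree-days, coldest-month temperature, annual precipitation) from
#' monthly present/glacial surfaces on the analysis grid.
#'
#' @param cfg A [synthetic_config()] describing the grid.
#' @param clim Output of [generate_climate_pair()] (or the same structure
#'   built from files).
#' @param thresholds Refugia thresholds, see [refugia_mask()].
#' @return List: `predictors` (`data.frame`, one row per cell in row-major
#'   order), `refugia` (the [refugia_mask()]), `velocity` (list of the two
#'   [climate_velocity()] results).
#' @export
build_predictors <- function(cfg, clim,
                             thresholds = list(gdd_min = 800,
                                               tcold_min = -15,
                                               psummer_min = 50)) {
  coords <- grid_cell_coords(cfg)
  gmean <- function(gs) {  # cellwise mean over a list of monthly grids
    g <- gs[[1]]
    climate_grid(Reduce(`+`, lapply(gs, `[[`, "values")) / length(gs),
                 g$cell_size_km, g$xll, g$yll, g$variable, g$epoch)
  }
  gsum <- function(gs) {
    g <- gs[[1]]
    climate_grid(Reduce(`+`, lapply(gs, `[[`, "values")),
                 g$cell_size_km, g$xll, g$yll, g$variable, g$epoch)
  }
  gmin <- function(gs) {
    g <- gs[[1]]
    climate_grid(Reduce(pmin, lapply(gs, `[[`, "values")),
                 g$cell_size_km, g$xll, g$yll, g$variable, g$epoch)
  }

  gdd_lgm <- growing_degree_days(clim$lgm$temperature)
  tcold_lgm <- gmin(clim$lgm$temperature)
  psummer_lgm <- gsum(clim$lgm$precipitation[6:8])
  refugia <- refugia_mask(gdd_lgm, tcold_lgm, psummer_lgm, thresholds)
  access <- accessibility(coords, refugia)

  t_pres <- gmean(clim$present$temperature)
  t_lgm <- gmean(clim$lgm$temperature)
  p_pres <- gsum(clim$present$precipitation)
  p_lgm <- gsum(clim$lgm$precipitation)
  vel_t <- climate_velocity(t_pres, t_lgm)
  vel_p <- climate_velocity(p_pres, p_lgm)

  predictors <- data.frame(
    accessibility = access,
    temp_velocity = grid_values(vel_t$velocity),
    prec_velocity = grid_values(vel_p$velocity),
    gdd = grid_values(growing_degree_days(clim$present$temperature)),
    tcold = grid_values(gmin(clim$present$temperature)),
    annual_prec = grid_values(p_pres))
  list(predictors = predictors, refugia = refugia,
       velocity = list(temperature = vel_t, precipitation = vel_p))
}

#' Run configuration for the end-to-end pipeline
#'
#' @param cfg A [synthetic_config()].
#' @param m Number of imputation replicates.
#' @param n_null Null randomizations per cell for SES (0 disables SES).
#' @param null_metrics Metrics to standardize against the null.
#' @param log10_predictors Skewed predictors log10-transformed before
#'   z-scoring.
#' @param max_predictors Optional cap on predictors per model.
#' @param out_dir Output directory (created if needed).
#' @return List of class `run_config`.
#' @export
run_config <- function(cfg = synthetic_config(), m = 3L, n_null = 0L,
                       null_metrics = "f_disp",
                       log10_predictors = c("temp_velocity", "prec_velocity",
                                            "annual_prec"),
                       max_predictors = NULL,
                       out_dir = tempfile("paleofd_run_")) {
  structure(list(cfg = cfg, m = as.integer(m), n_null = as.integer(n_null),
                 null_metrics = null_metrics,
                 log10_predictors = log10_predictors,
                 max_predictors = max_predictors, out_dir = out_dir),
            class = "run_config")
}

write_occurrence_triplets <- function(occ, path) {
  idx <- which(occ$m == 1L, arr.ind = TRUE)
  df <- data.frame(cell = rownames(occ$m)[idx[, 1]],
                   species = colnames(occ$m)[idx[, 2]])
  df <- df[order(df$cell, df$species), ]
  write.csv(df, path, row.names = FALSE)
}

#' Run the full pipeline
#'
#' Executes synthetic generation, trait imputation, functional diversity with
#' optional SES, predictor construction, and exhaustive multimodel inference
#' for both functional richness and dispersion; writes every stage as CSV (or
#' ESRI ASCII for grids) plus a JSON manifest of configuration and seeds.
#' Outputs are deterministic for a fixed configuration.
#'
#' @param config A [run_config()].
#' @return The output directory path, invisibly; the in-memory results are
#'   returned as the attribute `results`.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cfg <- config$cfg
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  traits <- stage("traits", generate_traits(cfg))
  masked <- stage("missingness",
                  inject_missingness(traits, cfg$missing_rates,
                                     seed = cfg$seed + 10L))
  write.csv(traits, file.path(out, "traits_complete.csv"), row.names = FALSE)
  write.csv(masked, file.path(out, "traits_observed.csv"), row.names = FALSE)
  mask <- as.data.frame(is.na(masked[.trait_names]))
  write.csv(cbind(species_id = masked$species_id, mask),
            file.path(out, "traits_missing_mask.csv"), row.names = FALSE)

  std <- stage("standardize", log_standardize(masked))
  imp <- stage("imputation",
               mice_impute(std, m = config$m, seed = cfg$seed + 20L))
  for (r in seq_len(imp$m))
    write.csv(imp$replicates[[r]],
              file.path(out, sprintf("imputed_%02d.csv", r)),
              row.names = FALSE)

  clim <- stage("climate", generate_climate_pair(cfg))
  bp <- stage("predictors", build_predictors(cfg, clim))
  write.csv(cbind(grid_cell_coords(cfg), bp$predictors),
            file.path(out, "predictors.csv"), row.names = FALSE)
  write_esri_ascii(climate_grid(bp$refugia$mask * 1, cfg$cell_size_km),
                   file.path(out, "refugia.asc"))

  occ <- stage("occurrences", generate_occurrences(cfg, bp$predictors, traits))
  write_occurrence_triplets(occ, file.path(out, "occurrences.csv"))

  W <- stage("weights", build_weights(occ$coords))
  fd <- stage("fd", fd_pipeline(occ, imp, n_null = config$n_null,
                                seed = cfg$seed + 30L,
                                null_metrics = config$null_metrics))
  rep_df <- do.call(rbind, lapply(seq_along(fd$replicates), function(r)
    cbind(replicate = r, fd$replicates[[r]])))
  write.csv(rep_df, file.path(out, "fd_replicates.csv"), row.names = FALSE)
  write.csv(fd$pooled, file.path(out, "fd_pooled.csv"), row.names = FALSE)

  infer <- list()
  for (metric in c("f_rich", "f_disp")) {
    yv <- lapply(fd$replicates, `[[`, metric)
    ok <- Reduce(`&`, lapply(yv, is.finite))
    Wm <- if (all(ok)) W else build_weights(occ$coords[ok, , drop = FALSE])
    inf <- stage(paste0("inference_", metric),
                 run_inference(bp$predictors[ok, , drop = FALSE],
                               lapply(yv, `[`, ok), Wm,
                               log10_predictors = config$log10_predictors,
                               max_predictors = config$max_predictors))
    infer[[metric]] <- inf
    write.csv(cbind(metric = metric, inf$importance),
              file.path(out, paste0("importance_", metric, ".csv")),
              row.names = FALSE)
    write.csv(cbind(metric = metric, inf$pseudo_r2),
              file.path(out, paste0("pseudo_r2_", metric, ".csv")),
              row.names = FALSE)
    write.csv(cbind(metric = metric, inf$coefficients),
              file.path(out, paste0("coefficients_", metric, ".csv")),
              row.names = FALSE)
    pr <- stage(paste0("partials_", metric),
                historical_partials(bp$predictors[ok, , drop = FALSE],
                                    lapply(yv, `[`, ok), Wm,
                                    config$log10_predictors))
    write.csv(pr, file.path(out, paste0("partial_residuals_", metric, ".csv")),
              row.names = FALSE)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("paleofd")),
    config = list(grid = c(cfg$grid_nrows, cfg$grid_ncols),
                  cell_size_km = cfg$cell_size_km,
                  n_species = cfg$n_species, n_genera = cfg$n_genera,
                  missing_rates = as.list(cfg$missing_rates),
                  richness_range = cfg$richness_range,
                  sar_lambda = cfg$sar_lambda, noise_sd = cfg$noise_sd,
                  m = config$m, n_null = config$n_null,
                  null_metrics = config$null_metrics,
                  log10_predictors = config$log10_predictors),
    seeds = list(base = cfg$seed, missingness = cfg$seed + 10L,
                 imputation = cfg$seed + 20L, null_model = cfg$seed + 30L))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  res <- list(traits = traits, imputed = imp, occ = occ, predictors = bp,
              weights = W, fd = fd, inference = infer)
  structure(invisible(out), results = res)
}

# partial residuals of the historical predictors from the all-predictor
# unimodal model, pooled over replicates
historical_partials <- function(pred, yv, W, log10_predictors,
                                historical = c("accessibility",
                                               "temp_velocity",
                                               "prec_velocity")) {
  Z <- as.matrix(pred)
  for (pr in intersect(log10_predictors, colnames(Z)))
    Z[, pr] <- log10(Z[, pr])
  Z <- scale(Z)
  spec <- setNames(rep(2L, ncol(Z)), colnames(Z))
  X <- spec_design(spec, Z)
  out <- list()
  for (h in intersect(historical, colnames(Z))) {
    M <- sapply(yv, function(y) {
      yz <- as.vector(scale(y))
      fit <- fit_sar_error(X, yz, W)
      partial_residuals(fit, X, yz, h)
    })
    M <- as.matrix(M)
    out[[h]] <- data.frame(predictor = h, x = Z[, h],
                           partial_mean = rowMeans(M),
                           partial_min = apply(M, 1L, min),
                           partial_max = apply(M, 1L, max))
  }
  do.call(rbind, out)
}
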