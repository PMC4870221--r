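# Functional diversity metrics, null-model randomization, SES, and the
# per-cell pipeline.

test_that("hull volume matches analytic solids", {
  tet <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  expect_equal(functional_richness(tet, d = 3), 1 / 6, tolerance = 1e-12)
  hyper <- as.matrix(expand.grid(0:1, 0:1, 0:1, 0:1))
  expect_equal(functional_richness(hyper, d = 4), 1, tolerance = 1e-12)
  square <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  expect_equal(functional_richness(square, d = 2), 1, tolerance = 1e-12)
})

test_that("hull volume is undefined for degenerate point sets", {
  expect_true(is.na(functional_richness(diag(4), d = 4)))       # n = d
  expect_true(is.na(functional_richness(matrix(0, 2, 4), d = 4)))
  coplanar <- cbind(matrix(rnorm(30), 10, 3), 0)                # flat in 4D
  expect_true(is.na(functional_richness(coplanar, d = 4)))
  expect_error(functional_richness(diag(3), d = 4), "expected 4")
})

test_that("hull volume is permutation-invariant and monotone under addition", {
  set.seed(1)
  for (i in 1:5) {
    P <- matrix(rnorm(60), 15, 4)
    v <- functional_richness(P)
    expect_equal(functional_richness(P[sample.int(15), ]), v,
                 tolerance = 1e-9)
    v2 <- functional_richness(rbind(P, rnorm(4)))
    expect_gte(v2, v - 1e-9)
  }
})

test_that("dispersion matches hand computations and its invariances", {
  expect_equal(functional_dispersion(matrix(1, 5, 4)), 0)
  expect_equal(functional_dispersion(rbind(c(0, 0), c(2, 0))), 1)
  square <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  expect_equal(functional_dispersion(square), sqrt(2) / 2, tolerance = 1e-12)
  set.seed(2)
  P <- matrix(rnorm(40), 10, 4)
  fd0 <- functional_dispersion(P)
  # translation invariance and linear scaling
  expect_equal(functional_dispersion(sweep(P, 2, c(3, -1, 2, 7), "+")), fd0,
               tolerance = 1e-12)
  expect_equal(functional_dispersion(2.5 * P), 2.5 * fd0, tolerance = 1e-12)
  # single species
  expect_equal(functional_dispersion(matrix(rnorm(4), 1, 4)), 0)
})

test_that("univariate range and SD are the population statistics", {
  expect_equal(univariate_range_sd(c(1, 1, 1)), c(range = 0, sd = 0))
  expect_equal(univariate_range_sd(c(0, 2)), c(range = 2, sd = 1))
  expect_equal(univariate_range_sd(c(0, 1, 2)),
               c(range = 2, sd = sqrt(2 / 3)), tolerance = 1e-6)
  expect_equal(univariate_range_sd(5), c(range = 0, sd = 0))
})

test_that("randomization preserves row sums and samples uniformly", {
  occ <- random_occurrence(30, sprintf("s%02d", 1:50), seed = 3)
  r1 <- randomize_occurrence(occ, seed = 4)
  expect_identical(rowSums(r1$m), rowSums(occ$m))
  expect_identical(sum(r1$m), sum(occ$m))
  expect_identical(randomize_occurrence(occ, seed = 4)$m, r1$m)
  # a cell holding the whole pool cannot change
  full <- occurrence_matrix(matrix(1L, 2, 10), data.frame(x = 1:2, y = 1:2))
  expect_identical(randomize_occurrence(full, seed = 1)$m, full$m)
  # inclusion frequency of each species ~ richness / pool
  one <- occurrence_matrix(matrix(c(rep(1L, 5), rep(0L, 45)), 1, 50),
                           data.frame(x = 0, y = 0))
  freq <- rowMeans(vapply(1:1000,
                          function(s) randomize_occurrence(one, s)$m[1, ],
                          numeric(50)))
  expect_true(all(abs(freq - 0.1) < 0.03))
})

test_that("randomization marginals agree with the vegan r0 null model", {
  skip_if_not_installed("vegan")
  occ <- random_occurrence(25, sprintf("s%02d", 1:40), seed = 5)
  ours <- Reduce(`+`, lapply(1:200, function(s)
    randomize_occurrence(occ, s)$m)) / 200
  nm <- vegan::nullmodel(occ$m, "r0")
  sims <- stats::simulate(nm, nsim = 200, seed = 6)
  theirs <- apply(sims, c(1, 2), mean)
  # both draw uniformly given row sums: cellwise expectation richness/pool
  expect_lt(max(abs(colMeans(ours) - colMeans(theirs))), 0.05)
  expect_equal(rowSums(ours), rowSums(occ$m), tolerance = 1e-12)
})

test_that("SES follows its defining formula", {
  expect_equal(ses(3, c(2, 3, 4)), 0)
  expect_equal(ses(5, c(2, 3, 4)), 2)
  expect_error(ses(1, c(2)), "at least 2")
  expect_warning(s <- ses(1, c(2, 2, 2)), "zero null SD")
  expect_true(is.na(s))
})

test_that("fd pipeline computes per-cell metrics and toggles SES", {
  cfg <- small_cfg(n_species = 60, n_genera = 12,
                   richness_range = c(6L, 12L))
  tr <- generate_traits(cfg)
  std <- log_standardize(tr)
  occ <- random_occurrence(20, std$species_id, c(6L, 12L), seed = 6)
  fd0 <- fd_pipeline(occ, std, n_null = 0)
  df <- fd0$replicates[[1]]
  expect_false(any(grepl("^ses_", names(df))))
  expect_identical(df$richness, unname(rowSums(occ$m)))
  expect_true(all(df$f_disp >= 0))
  expect_true(all(is.na(df$f_rich) | df$f_rich >= 0))
  # cells with identical composition get identical metrics
  m2 <- occ$m[c(1, 1, 2), ]
  rownames(m2) <- c("a", "b", "c")
  occ2 <- occurrence_matrix(m2, data.frame(x = 1:3, y = c(1, 5, 9)))
  fd2 <- fd_pipeline(occ2, std, n_null = 0)$replicates[[1]]
  expect_equal(fd2$f_rich[1], fd2$f_rich[2])
  expect_equal(fd2$f_disp[1], fd2$f_disp[2])
  # SES columns appear when nulls are requested
  fd1 <- fd_pipeline(occ, std, n_null = 10, seed = 7,
                     null_metrics = "f_disp")
  expect_true("ses_f_disp" %in% names(fd1$replicates[[1]]))
  expect_true("ses_f_disp_mean" %in% names(fd1$pooled))
  # unknown species are reported
  bad <- occ
  colnames(bad$m)[1] <- "ghost"
  expect_error(fd_pipeline(bad, std, n_null = 0), "ghost")
})

test_that("environmental filtering depresses hull volume relative to null", {
  cfg <- synthetic_config(grid_nrows = 5, grid_ncols = 5, n_species = 60,
                          n_genera = 12, richness_range = c(8L, 16L),
                          seed = 12)
  tr <- generate_traits(cfg)
  bp <- build_predictors(cfg, generate_climate_pair(cfg))
  occ <- generate_occurrences(cfg, bp$predictors, tr, filter_strength = 3)
  fd <- fd_pipeline(occ, log_standardize(tr), n_null = 60, seed = 14)
  s <- fd$replicates[[1]]$ses_f_rich
  f <- abs(as.vector(scale(bp$predictors$gdd)))
  strong <- f > quantile(f, 0.75)
  expect_lt(mean(s[strong], na.rm = TRUE), 0)
  expect_lt(mean(s[strong], na.rm = TRUE), mean(s[!strong], na.rm = TRUE))
})

test_that("functional richness is stable in the typical cell at low missingness", {
  # 1% MCAR per trait: the median per-cell relative change of the hull
  # volume stays below 5%; individual cells can move more when an imputed
  # species happens to be a hull vertex
  cfg <- synthetic_config(grid_nrows = 6, grid_ncols = 6, n_species = 200,
                          n_genera = 40, richness_range = c(12L, 40L),
                          seed = 2)
  tr <- generate_traits(cfg)
  bp <- build_predictors(cfg, generate_climate_pair(cfg))
  occ <- generate_occurrences(cfg, bp$predictors, tr)
  fd_full <- fd_pipeline(occ, log_standardize(tr),
                         n_null = 0)$replicates[[1]]$f_rich
  mk <- inject_missingness(tr, c(sla = 0.01, seed_mass = 0.01,
                                 max_height = 0.01, stem_density = 0.01),
                           seed = 3)
  imp <- mice_impute(log_standardize(mk), m = 3, seed = 4)
  fd_imp <- fd_pipeline(occ, imp, n_null = 0)$pooled$f_rich_mean
  rel <- abs(fd_imp - fd_full) / fd_full
  expect_lt(median(rel), 0.05)
})
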