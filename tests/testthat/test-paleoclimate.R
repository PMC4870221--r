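# Historical-predictor construction: ensembles, downscaling, degree-days,
# refugia, velocity, accessibility, and raster I/O.

test_that("ensemble mean matches a naive per-cell oracle", {
  expect_equal(ensemble_mean(list(const_grid(3)))$values, matrix(3, 5, 5))
  expect_equal(ensemble_mean(list(const_grid(1), const_grid(3)))$values,
               matrix(2, 5, 5))
  set.seed(1)
  gs <- lapply(1:13, function(i)
    climate_grid(matrix(rnorm(30), 5, 6), 50))
  em <- ensemble_mean(gs)
  naive <- matrix(0, 5, 6)
  for (i in 1:5) for (j in 1:6)
    naive[i, j] <- mean(vapply(gs, function(g) g$values[i, j], numeric(1)))
  expect_equal(em$values, naive, tolerance = 1e-12)
  # nodata ignored until every member is missing
  g1 <- climate_grid(matrix(c(NA, 2, NA, 4), 2, 2), 50)
  g2 <- climate_grid(matrix(c(NA, 4, 6, 8), 2, 2), 50)
  out <- ensemble_mean(list(g1, g2))$values
  expect_true(is.na(out[1, 1]))
  expect_equal(out[2, 1], 3)
  expect_equal(out[1, 2], 6)
  expect_error(ensemble_mean(list(const_grid(1), const_grid(1, nr = 4))),
               "georeference")
})

test_that("change-factor downscaling reproduces constant factors exactly", {
  fine <- climate_grid(matrix(rnorm(400, 10), 20, 20), 25,
                       variable = "temperature")
  cp <- const_grid(8, nr = 5, nc = 5, cs = 100, variable = "temperature")
  cl <- const_grid(-2, nr = 5, nc = 5, cs = 100, variable = "temperature")
  down <- change_factor_downscale(cl, cp, fine)
  expect_equal(down$values, fine$values - 10, tolerance = 1e-12)
  # identity anomaly
  same <- change_factor_downscale(cp, cp, fine)
  expect_equal(same$values, fine$values, tolerance = 1e-12)
  # constant precipitation ratio
  finep <- climate_grid(matrix(runif(400, 20, 80), 20, 20), 25,
                        variable = "precipitation")
  pl <- const_grid(30, nr = 5, nc = 5, cs = 100, variable = "precipitation")
  pp <- const_grid(60, nr = 5, nc = 5, cs = 100, variable = "precipitation")
  downp <- change_factor_downscale(pl, pp, finep)
  expect_equal(downp$values, finep$values * 0.5, tolerance = 1e-12)
  expect_true(all(downp$values >= 0))
  expect_error(change_factor_downscale(pl, pp, fine), "variable")
})

test_that("growing degree-days follow the 365-day accumulation", {
  base5 <- lapply(1:12, function(m) const_grid(5, variable = "temperature"))
  expect_equal(growing_degree_days(base5)$values, matrix(0, 5, 5))
  six <- lapply(1:12, function(m) const_grid(6, variable = "temperature"))
  expect_equal(growing_degree_days(six)$values, matrix(365, 5, 5))
  # seasonal cycle equals a naive per-cell loop
  set.seed(2)
  months <- lapply(1:12, function(m)
    climate_grid(matrix(10 * cos(2 * pi * (m - 7) / 12) + rnorm(25), 5, 5),
                 50, variable = "temperature"))
  gdd <- growing_degree_days(months)$values
  days <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
  naive <- matrix(0, 5, 5)
  for (i in 1:5) for (j in 1:5)
    for (m in 1:12)
      naive[i, j] <- naive[i, j] +
        max(0, months[[m]]$values[i, j] - 5) * days[m]
  expect_equal(gdd, naive, tolerance = 1e-12)
  expect_error(growing_degree_days(months[1:3]), "12 monthly")
})

test_that("refugia thresholds are inclusive and jointly required", {
  th <- list(gdd_min = 800, tcold_min = -15, psummer_min = 50)
  mk1 <- function(g, t, p)
    refugia_mask(const_grid(g, 1, 1), const_grid(t, 1, 1),
                 const_grid(p, 1, 1), th)$mask[1, 1]
  expect_true(mk1(800, -15, 50))       # boundary inclusive
  expect_false(mk1(799.9, -15, 50))    # one strict violation
  expect_false(mk1(800, -15.1, 50))
  expect_false(mk1(800, -15, 49.9))
  # random grids equal the naive triple-condition check
  set.seed(3)
  g <- climate_grid(matrix(runif(100, 0, 1600), 10, 10), 50)
  t <- climate_grid(matrix(runif(100, -30, 0), 10, 10), 50)
  p <- climate_grid(matrix(runif(100, 0, 100), 10, 10), 50)
  m <- refugia_mask(g, t, p, th)$mask
  expect_identical(m, g$values >= 800 & t$values >= -15 & p$values >= 50)
  # mask area shrinks as any threshold tightens
  for (i in 1:3) {
    th2 <- th
    th2[[i]] <- th2[[i]] + 10
    expect_lte(sum(refugia_mask(g, t, p, th2)$mask), sum(m))
  }
})

test_that("velocity equals trend over gradient on an exact plane", {
  # east-west plane at 0.01 degC/km, anomaly 2.1 degC over 21,000 years
  nr <- 6; nc <- 8; cs <- 50
  x <- (col(matrix(0, nr, nc)) - 0.5) * cs
  pres <- climate_grid(0.01 * x, cs, variable = "temperature")
  lgm <- climate_grid(0.01 * x - 2.1, cs, variable = "temperature")
  v <- climate_velocity(pres, lgm)
  inner <- v$velocity$values[2:(nr - 1), 2:(nc - 1)]
  expect_equal(inner, matrix(0.1, nr - 2, nc - 2), tolerance = 1e-9)
  expect_equal(v$log10_velocity$values[3, 3], -1, tolerance = 1e-9)
  # identical epochs: velocity 0 everywhere
  v0 <- climate_velocity(pres, pres)
  expect_true(all(v0$velocity$values == 0))
  # flat present surface: gradient floored and flagged
  flat <- const_grid(4, nr, nc, cs, variable = "temperature")
  flat_l <- const_grid(2, nr, nc, cs, variable = "temperature")
  vf <- climate_velocity(flat, flat_l)
  expect_true(all(vf$floored))
  expect_equal(vf$velocity$values[1, 1], (2 / 2100) / 1e-5, tolerance = 1e-9)
  expect_error(climate_velocity(pres, lgm, years = 0), "positive")
})

test_that("velocity invariances: level shift and anomaly doubling", {
  set.seed(4)
  pres <- climate_grid(matrix(rnorm(48, 10, 3), 6, 8), 50,
                       variable = "temperature")
  lgm <- climate_grid(pres$values - matrix(runif(48, 1, 6), 6, 8), 50,
                      variable = "temperature")
  v1 <- climate_velocity(pres, lgm)$velocity$values
  shift <- function(g, k) climate_grid(g$values + k, 50,
                                       variable = "temperature")
  v2 <- climate_velocity(shift(pres, 7), shift(lgm, 7))$velocity$values
  expect_equal(v1, v2, tolerance = 1e-12)
  lgm2 <- climate_grid(2 * lgm$values - pres$values, 50,
                       variable = "temperature")  # doubled anomaly
  v3 <- climate_velocity(pres, lgm2)$velocity$values
  expect_equal(v3, 2 * v1, tolerance = 1e-12)
})

test_that("accessibility sums inverse distances with a self-term", {
  cells <- data.frame(x = c(0, 500), y = c(0, 0))
  # two refugial cells at 100 km and 200 km from the first cell
  ref <- list(coords = data.frame(x = c(100, 200), y = c(0, 0)),
              cell_size_km = 50)
  a <- accessibility(cells, ref)
  expect_equal(a[1], 1 / 100 + 1 / 200, tolerance = 1e-12)
  expect_equal(a[2], 1 / 400 + 1 / 300, tolerance = 1e-12)
  # empty refugia: zeros with a warning
  expect_warning(z <- accessibility(cells, list(coords = data.frame(
    x = numeric(0), y = numeric(0)), cell_size_km = 50)), "no refugial")
  expect_equal(z, c(0, 0))
  # a refugial focal cell gains the self-term 1/(cs/2)
  ref2 <- list(coords = data.frame(x = c(0, 100)), cell_size_km = 50)
  ref2$coords$y <- c(0, 0)
  a2 <- accessibility(data.frame(x = 0, y = 0), ref2)
  expect_equal(a2, 1 / 25 + 1 / 100, tolerance = 1e-12)
  # additive over disjoint refugia sets
  refA <- list(coords = data.frame(x = 100, y = 0), cell_size_km = 50)
  refB <- list(coords = data.frame(x = 200, y = 0), cell_size_km = 50)
  expect_equal(accessibility(cells, refA) + accessibility(cells, refB), a,
               tolerance = 1e-12)
})

test_that("ESRI ASCII round-trips values, georeference and nodata", {
  set.seed(5)
  v <- matrix(rnorm(35), 5, 7)
  v[2, 3] <- NA
  g <- climate_grid(v, 50, xll = 100, yll = -200, variable = "temperature")
  p <- tempfile(fileext = ".asc")
  write_esri_ascii(g, p)
  g2 <- read_esri_ascii(p, variable = "temperature")
  expect_equal(g2$values, g$values, tolerance = 1e-12)
  expect_equal(g2$cell_size_km, 50)
  expect_equal(c(g2$xll, g2$yll), c(100, -200))
  unlink(p)
})
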