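test_that("parametric variograms honour gamma(0) = 0 and their sills", {
  d <- seq(0, 3e5, length.out = 200)
  for (fam in c("exponential", "spherical", "circular", "gaussian", "linear")) {
    g <- variogram_value(d, fam, c0 = 0.3, c = 1.2, a0 = 5e4)
    expect_equal(g[1], 0)
    expect_true(all(diff(g) >= -1e-12), info = fam)  # monotone non-decreasing
    if (fam != "linear") {
      expect_equal(g[length(g)], 1.5, tolerance = 0.05)  # approaches c0 + c
    }
  }
  expect_error(variogram_value(d, "exponential", -1, 1, 1), "c0")
})

test_that("empirical variogram reproduces hand-computed pair averages", {
  # 3 collinear points at x = 0, 1, 2 with residuals 0, 1, 2
  loc <- data.frame(x = c(0, 1, 2), y = c(0, 0, 0))
  emp <- empirical_variogram(c(0, 1, 2), loc, n_bins = 2, max_lag = 2,
                             min_pairs = 1)
  expect_equal(emp$gamma, c(0.5, 2.0))
  expect_equal(emp$np, c(2L, 1L))

  # constant residuals: zero semivariance everywhere
  loc2 <- toy_locations(12)
  emp2 <- empirical_variogram(rep(3, 12), loc2, min_pairs = 1)
  expect_true(all(emp2$gamma == 0))

  # permutation invariance
  set.seed(1)
  res <- rnorm(12)
  perm <- sample(12)
  e1 <- empirical_variogram(res, loc2, min_pairs = 1)
  e2 <- empirical_variogram(res[perm], loc2[perm, ], min_pairs = 1)
  expect_equal(e1$gamma, e2$gamma)
  expect_equal(e1$np, e2$np)
})

test_that("WLS refit of a noiseless exponential variogram recovers parameters", {
  emp <- emp_from_model("exponential", c0 = 1, c = 4, a0 = 3e4)
  v <- fit_variogram(emp, "exponential")
  expect_lt(abs(v$c0 - 1), 0.01)
  expect_lt(abs(v$c - 4) / 4, 0.01)
  expect_lt(abs(v$a0 - 3e4) / 3e4, 0.01)
  expect_equal(v$effective_range, 3 * v$a0)
})

test_that("spatially independent residuals are recognised as pure nugget", {
  loc <- toy_locations(96, side = 4.2e5, seed = 42)
  set.seed(42)
  hits <- 0
  for (i in 1:100) {
    emp <- empirical_variogram(rnorm(96), loc)
    v <- suppressWarnings(fit_variogram(emp, "exponential"))
    if (v$c0 > 0 && v$c < 0.1 * v$c0) hits <- hits + 1
  }
  expect_gte(hits, 90)
})

test_that("ML variogram fitting recovers planted fields better than binned WLS", {
  loc <- toy_locations(96, side = 4.2e5, seed = 8)
  set.seed(8)
  z <- simulate_gaussian_field(loc, variogram_model("exponential", 0.005, 0.1, 45000))
  vml <- fit_variogram_ml(z, loc, "exponential")
  expect_equal(vml$family, "exponential")
  expect_gt(vml$c, 0)      # structure detected
  expect_gt(vml$a0, 1e4)   # range on a physically sensible scale
  expect_lt(vml$a0, 2e5)
  # LRT guard: iid noise collapses to nugget
  set.seed(9)
  vnoise <- suppressWarnings(fit_variogram_ml(rnorm(96), loc, "exponential"))
  expect_equal(vnoise$c, 0)
})

test_that("ordinary kriging satisfies unbiasedness, exactness and the direct-solve oracle", {
  vgm <- variogram_model("exponential", c0 = 0, c = 1, a0 = 5e4)
  loc <- toy_locations(15, seed = 2)
  set.seed(2)
  res <- rnorm(15)

  # exactness at a data location when nugget = 0
  out <- krige(res, loc, vgm, loc[3, , drop = FALSE], return_weights = TRUE)
  expect_equal(out$estimate, res[3], tolerance = 1e-8)
  expect_equal(unname(attr(out, "weights")[1, 3]), 1, tolerance = 1e-8)
  expect_equal(out$variance, 0, tolerance = 1e-8)

  # weights sum to 1 for arbitrary targets
  tg <- toy_locations(7, seed = 3)
  outw <- krige(res, loc, vgm, tg, return_weights = TRUE)
  expect_true(all(abs(rowSums(attr(outw, "weights")) - 1) < 1e-10))
  expect_true(all(outw$variance > 0))

  # two stations 100 km apart, residuals (1, -1), target at the midpoint
  loc2 <- data.frame(x = c(0, 1e5), y = c(0, 0))
  v2 <- variogram_model("exponential", 0, 1, 5e4)
  mid <- krige(c(1, -1), loc2, v2, data.frame(x = 5e4, y = 0),
               return_weights = TRUE)
  expect_equal(as.numeric(attr(mid, "weights")), c(0.5, 0.5), tolerance = 1e-12)
  expect_equal(mid$estimate, 0, tolerance = 1e-12)

  # oracle equivalence on random instances, n <= 20, random families/params
  set.seed(4)
  for (i in 1:25) {
    n <- sample(5:20, 1)
    fam <- sample(c("exponential", "spherical", "gaussian"), 1)
    vi <- variogram_model(fam, runif(1, 0, 0.5), runif(1, 0.5, 2),
                          runif(1, 2e4, 1e5))
    li <- data.frame(x = runif(n, 0, 2e5), y = runif(n, 0, 2e5))
    ri <- rnorm(n)
    ti <- data.frame(x = runif(1, 0, 2e5), y = runif(1, 0, 2e5))
    got <- krige(ri, li, vi, ti)
    want <- ok_oracle(ri, li, vi, ti)
    expect_equal(got$estimate, want$estimate, tolerance = 1e-8)
    expect_equal(got$variance, want$variance, tolerance = 1e-6)
  }
})

test_that("kriging averages duplicated coordinates and needs two stations", {
  vgm <- variogram_model("exponential", 0.1, 1, 5e4)
  loc <- data.frame(x = c(0, 0, 1e5), y = c(0, 0, 0))
  out <- krige(c(2, 4, 1), loc, vgm, data.frame(x = 5e4, y = 0))
  # duplicates at the origin collapse to their mean (3)
  out2 <- krige(c(3, 1), data.frame(x = c(0, 1e5), y = c(0, 0)), vgm,
                data.frame(x = 5e4, y = 0))
  expect_equal(out$estimate, out2$estimate, tolerance = 1e-12)
  expect_error(krige(1, data.frame(x = 0, y = 0), vgm,
                     data.frame(x = 1, y = 1)), "2 stations")
})

test_that("LOOCV family selection prefers exponential on ties and honours single candidates", {
  loc <- toy_locations(40, side = 3e5, seed = 5)
  set.seed(5)
  z <- simulate_gaussian_field(loc, variogram_model("exponential", 0.01, 1, 4e4))
  one <- select_family_loocv(z, loc, families = "spherical")
  expect_equal(one$family, "spherical")
  sel <- select_family_loocv(z, loc)
  expect_true(sel$family %in% c("exponential", "spherical", "circular",
                                "gaussian", "linear"))
  expect_true(is.finite(sel$diagnostics$loocv_rmse))
  expect_length(sel$diagnostics$scores, 5)
})

test_that("daily surface stack flags thin days and reports per-day parameters", {
  set.seed(6)
  n <- 24; T_ <- 5
  loc <- toy_locations(n, side = 3e5, seed = 6)
  vgm_true <- variogram_model("exponential", 0.01, 1, 5e4)
  R <- vapply(1:T_, function(t) simulate_gaussian_field(loc, vgm_true),
              numeric(n))
  R[4:n, 3] <- NA  # day 3 has too few stations
  grid <- list(xmin = 0, xmax = 3e5, ymin = 0, ymax = 3e5, cell = 5e4)
  ds <- daily_surfaces(R, loc, grid, min_stations = 10)
  expect_equal(nrow(ds$params), T_)
  expect_false(ds$params$kriged[3])
  expect_true(all(ds$surfaces[, 3] == 0))
  expect_true(all(ds$params$kriged[-3]))
  # identical residuals across days give identical surfaces
  R2 <- matrix(rep(R[, 1], 2), n, 2)
  ds2 <- daily_surfaces(R2, loc, grid, min_stations = 10)
  expect_equal(ds2$surfaces[, 1], ds2$surfaces[, 2])
})

test_that("block means average points in the polygon and converge under refinement", {
  # two-cell polygon with values 10 and 20
  pts <- data.frame(x = c(0.5, 1.5), y = c(0.5, 0.5), value = c(10, 20))
  poly <- cbind(c(0, 2, 2, 0), c(0, 0, 1, 1))
  expect_equal(block_mean(pts, poly), 15)
  # constant surface
  pts$value <- 7
  expect_equal(block_mean(pts, poly), 7)
  expect_error(block_mean(pts, poly + 100), "intersect")

  # refinement on a smooth surface changes the estimate by < 1%
  f <- function(x, y) 50 + 10 * sin(x / 4e4) + 5 * cos(y / 6e4)
  poly2 <- cbind(c(2e4, 2.6e5, 2.6e5, 2e4), c(2e4, 2e4, 2.6e5, 2.6e5))
  bm <- vapply(c(2e4, 1e4), function(cell) {
    g <- grid_points(list(xmin = 0, xmax = 3e5, ymin = 0, ymax = 3e5,
                          cell = cell))
    g$value <- f(g$x, g$y)
    block_mean(g, poly2)
  }, numeric(1))
  expect_lt(abs(bm[2] - bm[1]) / abs(bm[1]), 0.01)
})

test_that("residual surface lookup transfers by day of year and flags extrapolation", {
  set.seed(7)
  loc <- toy_locations(12, seed = 7)
  R <- matrix(rnorm(24), 12, 2)
  ds <- daily_surfaces(R, loc, list(xmin = 0, xmax = 2e5, ymin = 0,
                                    ymax = 2e5, cell = 1e5), min_stations = 10)
  lk <- residual_surface_lookup(ds, 2)
  expect_true(attr(lk, "extrapolated"))
  expect_equal(lk$value, ds$surfaces[, 2])
  expect_error(residual_surface_lookup(ds, 3))
})
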