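test_that("metrics match hand computations and scale invariances", {
  o <- c(1, 2, 3)
  expect_equal(metrics(o, o), list(r2 = 1, rmse = 0, n = 3))
  m <- metrics(o, c(2, 2, 2))
  expect_equal(m$r2, 0)
  expect_equal(m$rmse, sqrt(2 / 3))
  # scaling both series by 10: RMSE x10, R2 unchanged
  set.seed(1)
  obs <- rnorm(50, 10); pred <- obs + rnorm(50, 0, 0.5)
  m1 <- metrics(obs, pred); m10 <- metrics(10 * obs, 10 * pred)
  expect_equal(m10$r2, m1$r2, tolerance = 1e-12)
  expect_equal(m10$rmse, 10 * m1$rmse, tolerance = 1e-12)
  # constant observed: R2 flagged as NA, RMSE still defined
  mc <- metrics(rep(2, 5), c(1, 2, 3, 2, 2))
  expect_true(is.na(mc$r2))
  expect_false(is.na(mc$rmse))
  expect_error(metrics(1, 1), "2 non-missing")
})

test_that("scenario grid matches the six-model design", {
  want <- list(
    c(engine = "single_gam", pm10 = FALSE, krige = FALSE),
    c(engine = "single_gam", pm10 = TRUE,  krige = FALSE),
    c(engine = "bagging",    pm10 = FALSE, krige = FALSE),
    c(engine = "bagging",    pm10 = FALSE, krige = TRUE),
    c(engine = "bagging",    pm10 = TRUE,  krige = FALSE),
    c(engine = "bagging",    pm10 = TRUE,  krige = TRUE)
  )
  for (id in 1:6) {
    cfg <- scenario_config(id)
    expect_equal(cfg$id, id)
    expect_equal(cfg$engine, unname(want[[id]]["engine"]))
    expect_equal(cfg$use_pm10, as.logical(want[[id]]["pm10"]))
    expect_equal(cfg$use_residual_kriging, as.logical(want[[id]]["krige"]))
  }
  expect_error(scenario_config(7))
})

test_that("k-fold CV is near-perfect on a deterministic response and near-zero on noise", {
  set.seed(2)
  n <- 400
  df <- data.frame(station_id = sample(sprintf("S%d", 1:8), n, TRUE),
                   x1 = runif(n, -2, 2))
  df$log_pm25 <- 3 + 0.5 * sin(2 * df$x1)
  cv <- kfold_cv(df, "x1", k = 5, repeats = 2, seed = 1)
  expect_gt(cv$r2, 0.999)
  expect_lt(cv$rmse, 0.2)
  expect_equal(nrow(cv$per_repeat), 2)

  # mean-only information: pooled R2 near zero
  dfn <- df
  dfn$log_pm25 <- 3 + rnorm(n, 0, 0.3)
  cvn <- kfold_cv(dfn, "x1", k = 5, repeats = 2, seed = 1)
  expect_lt(abs(cvn$r2), 0.1)

  # repeat-to-repeat stability on a well-specified fit
  expect_lt(cv$r2_sd, 0.05)
  expect_error(kfold_cv(df, "x1", k = 500, repeats = 1), "k exceeds")
})

test_that("station-level folds hold out whole stations", {
  set.seed(3)
  n <- 240
  df <- data.frame(station_id = rep(sprintf("S%d", 1:12), each = 20),
                   x1 = runif(n, -2, 2))
  df$log_pm25 <- 3 + 0.4 * df$x1 + rnorm(n, 0, 0.1)
  cv <- kfold_cv(df, "x1", k = 4, repeats = 1, seed = 2,
                 stratify_by_station = TRUE)
  expect_true(is.finite(cv$r2))
})

test_that("a deterministic PM10 link makes the PM10 scenario near-perfect", {
  set.seed(4)
  n <- 500
  df <- data.frame(station_id = sample(sprintf("S%d", 1:10), n, TRUE),
                   day = sample(1:50, n, TRUE),
                   x = runif(n, 0, 1e5), y = runif(n, 0, 1e5),
                   x1 = runif(n))
  df$log_pm25 <- 4 + 0.3 * df$x1 + rnorm(n, 0, 0.3)
  df$log_pm10 <- df$log_pm25 - log(0.57)
  # mgcv emits step-failure warnings on an (intentionally) perfect fit
  rep2 <- suppressWarnings(
    run_scenario(scenario_config(2), df, "x1", cv_repeats = 1, seed = 1))
  expect_gt(rep2$r2, 0.999)
})

test_that("scenario runs are deterministic under a fixed seed", {
  df <- toy_long(300, seed = 5)
  a <- run_scenario(scenario_config(3), df, c("x1", "x2"), B = 3, seed = 9)
  b <- run_scenario(scenario_config(3), df, c("x1", "x2"), B = 3, seed = 9)
  expect_identical(a$r2, b$r2)
  expect_identical(a$rmse, b$rmse)
  expect_identical(a$predictions$pred_log, b$predictions$pred_log)
})

test_that("residual kriging on planted spatial structure lifts OOB accuracy", {
  # compact end-to-end check at reduced size; the full-size ordering is
  # exercised in the acceptance suite
  cfg <- sim_config(n_stations = 30, n_days = 60, seed = 11)
  dat <- generate_panel(cfg)
  imp <- svd_impute(log_transform(dat$pm25))
  basis <- smooth_basis(extract_basis(imp), 8)
  long <- panel_to_long(dat$pm25, dat$covariates, basis, dat$pm10)
  terms <- c("f1", "f2", "temp", "humid", "road", "elev")
  r3 <- run_scenario(scenario_config(3), long, terms, B = 6, seed = 2,
                     min_stations = 10)
  r4 <- run_scenario(scenario_config(4), long, terms, B = 6, seed = 2,
                     min_stations = 10)
  expect_gt(r4$r2, r3$r2)
  expect_lt(r4$rmse, r3$rmse)
  expect_true(any(r4$vgm_params$kriged))
})
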