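test_that("additive fit recovers a planted smooth on the interior", {
  set.seed(1)
  n <- 2000
  noise_sd <- 0.3
  x1 <- runif(n, -2, 2)
  df <- data.frame(log_pm25 = 4 + sin(2 * x1) + rnorm(n, 0, noise_sd), x1 = x1)
  fit <- fit_additive(df, smooth_terms = "x1")
  # pointwise comparison on the interior of the covariate range
  grid <- data.frame(x1 = seq(-1.6, 1.6, length.out = 100))
  est <- predict(fit, grid)
  truth <- 4 + sin(2 * grid$x1)
  rmse <- sqrt(mean((est - truth)^2))
  expect_lt(rmse, 3 * noise_sd / sqrt(n) * sqrt(sum(fit$model$edf)))
  expect_gt(fit$r2_train, 0.5)
})

test_that("additive fit nests the linear fit and handles degenerate responses", {
  set.seed(2)
  n <- 300
  df <- data.frame(x1 = runif(n), x2 = runif(n))
  df$log_pm25 <- 1 + 2 * df$x1 - df$x2 + rnorm(n, 0, 0.1)
  gam_fit <- fit_additive(df, smooth_terms = c("x1", "x2"))
  lin <- lm(log_pm25 ~ x1 + x2, data = df)
  r2_lin <- summary(lin)$r.squared
  expect_gte(gam_fit$r2_train, r2_lin - 0.01)

  # constant response: zero R2, flat fit
  dfc <- data.frame(log_pm25 = rep(2, 100), x1 = runif(100))
  fitc <- fit_additive(dfc, smooth_terms = "x1")
  expect_equal(fitc$r2_train, 0)
  expect_lt(sd(fitted(fitc$model)), 1e-8)

  expect_error(fit_additive(df, smooth_terms = "nope"), "nope")
  expect_error(fit_additive(df), "no model terms")
})

test_that("prediction flags extrapolation and names missing columns", {
  df <- toy_long(300, seed = 3)
  fit <- fit_additive(df, smooth_terms = c("x1", "x2"))
  p <- predict(fit, data.frame(x1 = c(0, 10), x2 = c(0.5, 0.5)))
  expect_identical(attr(p, "extrapolated"), c(FALSE, TRUE))
  expect_error(predict(fit, data.frame(x1 = 1)), "x2")
})

test_that("a bivariate wind smooth captures a joint wind-vector effect", {
  set.seed(8)
  n <- 600
  we <- rnorm(n, 0, 3); wn <- rnorm(n, 0, 3)
  # effect depends on the wind vector jointly (speed-weighted direction)
  df <- data.frame(log_pm25 = 4 - 0.04 * we * wn + rnorm(n, 0, 0.1),
                   wind_e = we, wind_n = wn)
  fit <- fit_additive(df, wind_pair = c("wind_e", "wind_n"))
  expect_gt(fit$r2_train, 0.5)
  add_fit <- fit_additive(df, smooth_terms = c("wind_e", "wind_n"))
  expect_gt(fit$r2_train, add_fit$r2_train)  # interaction needs the 2-d smooth
})

test_that("variance decomposition attributes explained variance to terms", {
  set.seed(9)
  n <- 400
  df <- data.frame(x1 = runif(n, -2, 2), x2 = runif(n, -2, 2))
  df$log_pm25 <- 3 + sin(2 * df$x1) + 0.1 * df$x2 + rnorm(n, 0, 0.2)
  vd <- variance_decomposition(df, smooth_terms = c("x1", "x2"))
  expect_equal(vd$term, c("x1", "x2"))
  # the strong term dominates on both attributions
  expect_gt(vd$univariate_r2[1], vd$univariate_r2[2])
  expect_gt(vd$multivariate_drop[1], vd$multivariate_drop[2])
  expect_gt(attr(vd, "full_r2"), vd$univariate_r2[1])
})

test_that("ensemble weights follow w_i = R2_i^2 / sum(R2^2)", {
  expect_equal(ensemble_weights(c(0.5, 1.0)), c(0.2, 0.8))
  expect_equal(ensemble_weights(rep(0.7, 5)), rep(0.2, 5))
  set.seed(4)
  r2 <- runif(20)
  expect_equal(sum(ensemble_weights(r2)), 1)
  expect_warning(w0 <- ensemble_weights(c(0, 0, 0)), "uniform")
  expect_equal(w0, rep(1 / 3, 3))
  # members worse than the mean get zero weight
  expect_equal(ensemble_weights(c(-0.5, 1.0)), c(0, 1))
  expect_error(ensemble_weights(c(0.5, 1.2)), "above 1")
})

test_that("weighted ensemble SD matches its closed form", {
  # unanimous members: zero spread
  P <- matrix(2, 3, 4)
  st <- weighted_ensemble_stats(P, rep(0.25, 4))
  expect_equal(st$mean_log, rep(2, 3))
  expect_equal(st$sd_log, rep(0, 3))

  # two members, equal weights, predictions (1, 3): sd = sqrt(2)
  st2 <- weighted_ensemble_stats(matrix(c(1, 3), 1, 2), c(0.5, 0.5))
  expect_equal(st2$mean_log, 2)
  expect_equal(st2$sd_log, sqrt(2), tolerance = 1e-12)

  # single nonzero weight: M = 1, sd defined as 0
  st3 <- weighted_ensemble_stats(matrix(c(5, 99), 1, 2), c(1, 0))
  expect_equal(st3$mean_log, 5)
  expect_equal(st3$sd_log, 0)
  expect_equal(st3$M, 1)

  # equal weights reduce to the ordinary sample SD
  set.seed(5)
  preds <- matrix(rnorm(8 * 6), 8, 6)
  st4 <- weighted_ensemble_stats(preds, rep(1 / 6, 6))
  expect_equal(st4$sd_log, apply(preds, 1, sd), tolerance = 1e-12)

  # weighted mean bounded by member range, permutation invariant
  w <- ensemble_weights(runif(6, 0.2, 0.9))
  st5 <- weighted_ensemble_stats(preds, w)
  expect_true(all(st5$mean_log >= apply(preds, 1, min) - 1e-12))
  expect_true(all(st5$mean_log <= apply(preds, 1, max) + 1e-12))
  perm <- sample(6)
  st6 <- weighted_ensemble_stats(preds[, perm], w[perm])
  expect_equal(st6$mean_log, st5$mean_log, tolerance = 1e-12)
  expect_equal(st6$sd_log, st5$sd_log, tolerance = 1e-12)
})

test_that("bagging is deterministic under seed and degenerates to one model at B = 1", {
  df <- toy_long(250, seed = 6)
  e1 <- bagging_fit(df, smooth_terms = c("x1", "x2"), B = 5, seed = 42)
  e2 <- bagging_fit(df, smooth_terms = c("x1", "x2"), B = 5, seed = 42)
  expect_identical(e1$weights, e2$weights)
  nd <- df[1:20, ]
  expect_equal(predict(e1, nd)$mean_log, predict(e2, nd)$mean_log,
               tolerance = 1e-15)

  eb1 <- bagging_fit(df, smooth_terms = c("x1", "x2"), B = 1, seed = 7)
  expect_equal(eb1$weights, 1)
  single <- predict(eb1$members[[1]], nd)
  ens <- predict(eb1, nd)
  expect_equal(ens$mean_log, as.numeric(single), tolerance = 1e-12)
  expect_equal(ens$sd_log, rep(0, 20))
})

test_that("out-of-bag machinery never scores a member on its own training rows", {
  df <- toy_long(200, seed = 7)
  ens <- bagging_fit(df, smooth_terms = c("x1", "x2"), B = 8, seed = 1)
  for (b in seq_len(ens$B)) {
    oob <- setdiff(seq_len(ens$n), unique(ens$inbag[[b]]))
    expect_length(intersect(oob, unique(ens$inbag[[b]])), 0)
    # expected OOB share ~ 36.8%
    expect_gt(length(oob) / ens$n, 0.25)
    expect_lt(length(oob) / ens$n, 0.48)
  }
  oobp <- oob_ensemble_predictions(ens, df)
  expect_equal(nrow(oobp), nrow(df))
  expect_true(all(oobp$n_members[!is.na(oobp$mean_log)] >= 1))
})

test_that("bootstrap unique fraction matches the closed form and simulation", {
  bf <- bootstrap_unique_fraction(35040)
  expect_equal(bf$expected, 1 - (1 - 1 / 35040)^35040, tolerance = 1e-15)
  expect_equal(bf$expected, 1 - exp(-1), tolerance = 1e-4)
  bf2 <- bootstrap_unique_fraction(500, simulate = 200, seed = 9)
  expect_lt(abs(bf2$empirical - bf2$expected), 0.01)
})
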