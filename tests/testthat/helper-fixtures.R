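# Fixture builders shared across test files. Everything is generated in code;
# sizes are kept small so the default run stays fast.

# small positive-valued panel with optional missingness
toy_panel <- function(n_stations = 5, n_days = 8, seed = 1, missing = 0) {
  set.seed(seed)
  st <- data.frame(id = sprintf("A%02d", seq_len(n_stations)),
                   lon = 116 + runif(n_stations), lat = 36 + runif(n_stations))
  vals <- matrix(exp(rnorm(n_stations * n_days, log(60), 0.4)),
                 n_stations, n_days)
  if (missing > 0) vals[sample(length(vals), round(missing * length(vals)))] <- NA
  pm_panel(st, seq_len(n_days), vals, "PM25")
}

# modelling table with one planted smooth effect and noise
toy_long <- function(n = 400, seed = 1, noise_sd = 0.2) {
  set.seed(seed)
  x1 <- runif(n, -2, 2)
  x2 <- runif(n, 0, 1)
  data.frame(
    station_id = sample(sprintf("S%02d", 1:10), n, replace = TRUE),
    day = sample(1:30, n, replace = TRUE),
    x = runif(n, 0, 1e5), y = runif(n, 0, 1e5),
    x1 = x1, x2 = x2,
    log_pm25 = 4 + sin(2 * x1) + 0.5 * x2 + rnorm(n, 0, noise_sd)
  )
}

# scattered planar locations in a square of given side (metres)
toy_locations <- function(n = 20, side = 2e5, seed = 1) {
  set.seed(seed)
  data.frame(x = runif(n, 0, side), y = runif(n, 0, side))
}

# exact empirical-variogram object from a model (inverse-crime fixture)
emp_from_model <- function(family, c0, c, a0, d = seq(5e3, 1.2e5, length.out = 8),
                           np = rep(50, length(d))) {
  structure(list(dist = d,
                 gamma = variogram_value(d, family, c0, c, a0),
                 np = np, max_lag = max(d), n_bins = length(d), n_used = 20),
            class = "pm_empirical_variogram")
}

# brute-force ordinary-kriging oracle: builds and solves the augmented
# variogram system directly, independently of krige()
ok_oracle <- function(residuals, locations, vgm, target) {
  loc <- as.matrix(locations[, c("x", "y")])
  n <- nrow(loc)
  G <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) {
      dij <- sqrt(sum((loc[i, ] - loc[j, ])^2))
      G[i, j] <- variogram_value(dij, vgm$family, vgm$c0, vgm$c, vgm$a0)
    }
  }
  A <- cbind(rbind(G, 1), c(rep(1, n), 0))
  g0 <- vapply(seq_len(n), function(i) {
    d0 <- sqrt(sum((loc[i, ] - as.numeric(target))^2))
    variogram_value(d0, vgm$family, vgm$c0, vgm$c, vgm$a0)
  }, numeric(1))
  sol <- solve(A, c(g0, 1))
  list(estimate = sum(sol[1:n] * residuals),
       weights = sol[1:n],
       variance = sum(sol[1:n] * g0) + sol[n + 1])
}

# shared cache so expensive end-to-end computations are reused across
# acceptance blocks in a single run
.pm_test_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .pm_test_cache)) {
    assign(key, force(expr), envir = .pm_test_cache)
  }
  get(key, envir = .pm_test_cache)
}
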