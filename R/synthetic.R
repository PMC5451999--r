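# Synthetic monitoring data with the statistical structure the estimation
# method assumes: a clustered provincial station network, winter-high seasonal
# log-concentration signal, known smooth covariate effects, daily Gaussian
# random residual fields with a seasonal exponential-variogram schedule, a
# PM2.5/PM10 ratio centred on 0.57, and ~4% completely-at-random missingness.
# The noiseless truth is stored alongside the panel for recovery tests.

#' Simulation configuration
#'
#' Defaults emulate a provincial network: 96 stations in ~17 urban clusters
#' over a ~420 x 420 km domain, 365 days, winter-high seasonality on the log
#' scale, an exponential residual variogram whose range and sill shrink from
#' winter to summer (2:1 range schedule), a PM2.5/PM10 ratio with mean 0.57
#' and SD 0.10 varying mostly by day, and 4% missing daily values.
#'
#' @param n_stations number of stations.
#' @param n_days number of days (365 = one non-leap year).
#' @param bbox_km domain c(xmin, xmax, ymin, ymax) in km.
#' @param n_clusters number of urban clusters stations group into.
#' @param intercept_log mean log concentration (log ug/m3).
#' @param seasonal_amplitude amplitudes c(a1, a2) of the annual and
#'   semi-annual harmonics on the log scale.
#' @param vgm_winter,vgm_summer exponential-variogram parameters
#'   list(c0, c, a0_km) for mid-winter and mid-summer; each day interpolates
#'   between them on an annual cosine.
#' @param noise_sd iid measurement noise SD on the log scale.
#' @param ratio_mean,ratio_sd PM2.5/PM10 ratio mean and (total) SD.
#' @param ratio_seasonal_amplitude amplitude of the ratio's annual cycle
#'   (winter-high).
#' @param ratio_station_sd SD of the per-record ratio perturbation around the
#'   day's common ratio.
#' @param missing_fraction completely-at-random missing rate.
#' @param lonlat_origin c(lon, lat) mapped to the domain centre.
#' @param seed RNG seed.
#' @return list of class `pm_sim_config`.
#' @export
sim_config <- function(n_stations = 96, n_days = 365,
                       bbox_km = c(0, 420, 0, 420), n_clusters = 17,
                       intercept_log = log(65),
                       seasonal_amplitude = c(0.60, 0.12),
                       vgm_winter = list(c0 = 0.008, c = 0.12, a0_km = 60),
                       vgm_summer = list(c0 = 0.004, c = 0.06, a0_km = 30),
                       noise_sd = 0.05,
                       ratio_mean = 0.57, ratio_sd = 0.10,
                       ratio_seasonal_amplitude = 0.04,
                       ratio_station_sd = 0.03,
                       missing_fraction = 0.04,
                       lonlat_origin = c(117.5, 36.3),
                       seed = 1) {
  stopifnot(n_stations >= 2, n_days >= 2,
            vgm_winter$c0 >= 0, vgm_winter$c >= 0, vgm_winter$a0_km > 0,
            vgm_summer$c0 >= 0, vgm_summer$c >= 0, vgm_summer$a0_km > 0,
            ratio_mean > 0, ratio_mean < 1,
            missing_fraction >= 0, missing_fraction < 0.5)
  if (bbox_km[2] <= bbox_km[1] || bbox_km[4] <= bbox_km[3]) {
    stop("degenerate bounding box")
  }
  structure(as.list(environment()), class = "pm_sim_config")
}

#' Generate a clustered monitoring network
#'
#' Cluster centres are uniform in the (margin-inset) bounding box; stations
#' scatter around a sampled centre with Gaussian spread and are clipped to the
#' box. Coordinates are deterministic under the config seed.
#'
#' @param config a [sim_config()].
#' @return station data.frame (id, lon, lat, x, y) with x/y in metres; the
#'   projection origin is stored in the `"origin"` attribute.
#' @export
generate_network <- function(config) {
  stopifnot(inherits(config, "pm_sim_config"))
  set.seed(config$seed)
  bb <- config$bbox_km * 1000
  w <- bb[2] - bb[1]; h <- bb[4] - bb[3]
  margin <- 0.08
  cx <- runif(config$n_clusters, bb[1] + margin * w, bb[2] - margin * w)
  cy <- runif(config$n_clusters, bb[3] + margin * h, bb[4] - margin * h)
  spread <- 0.04 * min(w, h)
  repeat {
    cl <- sample.int(config$n_clusters, config$n_stations, replace = TRUE)
    x <- pmin(pmax(cx[cl] + rnorm(config$n_stations, 0, spread), bb[1]), bb[2])
    y <- pmin(pmax(cy[cl] + rnorm(config$n_stations, 0, spread), bb[3]), bb[4])
    if (!anyDuplicated(cbind(x, y))) break
  }
  # planar coords are relative to the domain centre
  xc <- x - mean(c(bb[1], bb[2]))
  yc <- y - mean(c(bb[3], bb[4]))
  ll <- unproject_xy(xc, yc, config$lonlat_origin)
  data.frame(id = sprintf("S%03d", seq_len(config$n_stations)),
             lon = ll$lon, lat = ll$lat, x = xc, y = yc,
             stringsAsFactors = FALSE)
}

#' Daily true variogram parameters under the seasonal schedule
#'
#' Each parameter interpolates between its mid-winter (day 15) and mid-summer
#' value on an annual cosine, so winter days carry the larger range/sill.
#'
#' @param config a [sim_config()].
#' @param days day indices.
#' @return data.frame (day, c0, c, a0) with a0 in metres.
#' @export
true_variogram_schedule <- function(config, days = seq_len(config$n_days)) {
  wgt <- (1 + cos(2 * pi * (days - 15) / 365)) / 2  # 1 mid-winter, 0 mid-summer
  data.frame(
    day = days,
    c0 = config$vgm_summer$c0 + wgt * (config$vgm_winter$c0 - config$vgm_summer$c0),
    c = config$vgm_summer$c + wgt * (config$vgm_winter$c - config$vgm_summer$c),
    a0 = 1000 * (config$vgm_summer$a0_km +
                   wgt * (config$vgm_winter$a0_km - config$vgm_summer$a0_km))
  )
}

#' Simulate a Gaussian random field at station locations
#'
#' Draws one realisation of a zero-mean field whose covariance follows the
#' variogram: C(d) = c * exp(-d/a0) for the structured part (Cholesky
#' factorization of the station covariance matrix) plus iid N(0, c0) nugget
#' noise. Uses the current RNG state.
#'
#' @param locations planar coordinates (columns x, y).
#' @param vgm a `pm_variogram` (exponential family).
#' @return numeric vector, one value per location.
#' @export
simulate_gaussian_field <- function(locations, vgm) {
  stopifnot(inherits(vgm, "pm_variogram"))
  loc <- as.matrix(as.data.frame(locations)[, c("x", "y")])
  n <- nrow(loc)
  z <- numeric(n)
  if (vgm$c > 0) {
    D <- as.matrix(dist(loc))
    C <- vgm$c * exp(-D / vgm$a0)
    diag(C) <- diag(C) + 1e-10 * vgm$c
    L <- chol(C)
    z <- as.numeric(t(L) %*% rnorm(n))
  }
  if (vgm$c0 > 0) z <- z + rnorm(n, 0, sqrt(vgm$c0))
  z
}

# true smooth covariate effects (centred over typical covariate ranges);
# g_temp is deliberately non-monotone so the additive fitter's advantage over
# a linear fit is testable
sim_effect_functions <- function() {
  list(
    temp = function(v) 0.20 * exp(-((v - 10) / 12)^2) - 0.115,
    humid = function(v) 0.15 * tanh((v - 60) / 20),
    road = function(v) 0.12 * log1p(v) - 0.20,
    elev = function(v) -0.0004 * (v - 150)
  )
}

#' Generate a full synthetic year of measurements
#'
#' log PM2.5(s,t) = intercept + seasonal harmonics (winter-high) + smooth
#' covariate effects + a daily Gaussian random field drawn from that day's
#' exponential variogram + iid noise. PM10 = PM2.5 / ratio with the ratio
#' drawn per day around its seasonal mean plus a small per-record
#' perturbation, truncated to (0.2, 0.95). Missingness is applied completely
#' at random to each panel.
#'
#' @param config a [sim_config()].
#' @return list: `pm25`, `pm10` (`pm_panel`s), `covariates`
#'   ([covariate_table()]), `stations`, and `truth` (noiseless log-mean
#'   matrix, field matrix, daily variogram parameters, effect functions,
#'   attainable R2 on the log scale).
#' @export
generate_panel <- function(config) {
  stopifnot(inherits(config, "pm_sim_config"))
  stations <- generate_network(config)   # consumes config$seed deterministically
  set.seed(config$seed + 1L)
  n <- config$n_stations
  T_ <- config$n_days
  days <- seq_len(T_)
  a <- config$seasonal_amplitude
  seasonal <- a[1] * cos(2 * pi * (days - 15) / 365) +
    a[2] * cos(4 * pi * (days - 15) / 365 + 0.8)

  # covariates: two spatiotemporal (temperature-, humidity-like), two spatial
  # (road density-, elevation-like)
  eff <- sim_effect_functions()
  temp_day <- 14 - 13 * cos(2 * pi * (days - 200) / 365)
  temp <- outer(rnorm(n, 0, 1.5), rep(1, T_)) +
    outer(rep(1, n), temp_day) + matrix(rnorm(n * T_, 0, 2), n, T_)
  humid <- pmin(pmax(outer(rep(1, n), 60 + 15 * sin(2 * pi * (days - 130) / 365)) +
                       matrix(rnorm(n * T_, 0, 8), n, T_), 5), 100)
  road <- pmax(rexp(n, 1 / 4) + rnorm(n, 0, 0.5), 0)
  elev <- pmax(50 + 0.3 * (stations$y / 1000) + rnorm(n, 0, 60), 0)

  effects <- eff$temp(temp) + eff$humid(humid) +
    outer(eff$road(road) + eff$elev(elev), rep(1, T_))

  sched <- true_variogram_schedule(config, days)
  field <- matrix(0, n, T_)
  for (t in days) {
    vgm_t <- variogram_model("exponential", sched$c0[t], sched$c[t],
                             sched$a0[t], day = t)
    field[, t] <- simulate_gaussian_field(stations[, c("x", "y")], vgm_t)
  }

  mu_log <- config$intercept_log + outer(rep(1, n), seasonal) + effects
  log_pm25 <- mu_log + field + matrix(rnorm(n * T_, 0, config$noise_sd), n, T_)
  pm25 <- exp(log_pm25)

  # day-common seasonal ratio + per-record perturbation, truncated
  day_noise_sd <- sqrt(max(config$ratio_sd^2 -
                             config$ratio_seasonal_amplitude^2 / 2 -
                             config$ratio_station_sd^2, 0))
  ratio_day <- config$ratio_mean +
    config$ratio_seasonal_amplitude * cos(2 * pi * (days - 15) / 365) +
    rnorm(T_, 0, day_noise_sd)
  ratio <- outer(rep(1, n), ratio_day) +
    matrix(rnorm(n * T_, 0, config$ratio_station_sd), n, T_)
  ratio <- pmin(pmax(ratio, 0.2), 0.95)
  pm10 <- pm25 / ratio

  miss25 <- matrix(runif(n * T_) < config$missing_fraction, n, T_)
  miss10 <- matrix(runif(n * T_) < config$missing_fraction, n, T_)
  v25 <- pm25; v25[miss25] <- NA
  v10 <- pm10; v10[miss10] <- NA

  st <- stations
  panel25 <- pm_panel(st, days, v25, "PM25", origin = config$lonlat_origin)
  panel10 <- pm_panel(st, days, v10, "PM10", origin = config$lonlat_origin)
  # keep simulated planar coordinates (projection from lon/lat reproduces
  # them only approximately at provincial scale)
  panel25$stations$x <- st$x; panel25$stations$y <- st$y
  panel10$stations$x <- st$x; panel10$stations$y <- st$y

  covs <- covariate_table(
    spatial = data.frame(station_id = st$id, road = road, elev = elev,
                         stringsAsFactors = FALSE),
    spatiotemporal = data.frame(
      station_id = rep(st$id, T_),
      day = rep(days, each = n),
      temp = as.numeric(temp),
      humid = as.numeric(humid),
      stringsAsFactors = FALSE),
    units = c(road = "km within 10 km buffer", elev = "m",
              temp = "degC", humid = "%")
  )

  noise_var <- config$noise_sd^2
  total_var <- var(as.numeric(log_pm25))
  truth <- list(mu_log = mu_log, field = field, seasonal = seasonal,
                variogram_schedule = sched, effects = eff,
                ratio_day = ratio_day,
                field_variance_fraction = var(as.numeric(field)) / total_var,
                attainable_r2_log = 1 - noise_var / total_var)
  list(pm25 = panel25, pm10 = panel10, covariates = covs,
       stations = st, truth = truth)
}

#' End-to-end planted-signal recovery report
#'
#' Runs the full pipeline (impute, basis, bagged ensemble, out-of-bag
#' residual kriging — the bagging + kriging scenario) on a generated dataset
#' and reports how well the planted structure is recovered: out-of-bag R2 vs
#' the attainable R2 from the stored truth, per-day variogram range recovery
#' (median relative error of a0 against the planted schedule), and its
#' winter/summer medians.
#'
#' @param config a [sim_config()].
#' @param B ensemble size.
#' @param seed pipeline RNG seed (generation uses `config$seed`).
#' @return list: `oob_r2`, `kriged_r2`, `attainable_r2`,
#'   `a0_median_rel_error`, `winter_median_a0`, `summer_median_a0`,
#'   `vgm_params`, `basis_variance_fraction`.
#' @export
planted_recovery_suite <- function(config, B = 25, seed = 1) {
  dat <- generate_panel(config)
  imp <- svd_impute(log_transform(dat$pm25))
  basis <- smooth_basis(extract_basis(imp))
  long <- panel_to_long(dat$pm25, dat$covariates, basis, dat$pm10)
  terms <- c("f1", "f2", "temp", "humid", "road", "elev")
  cfg4 <- scenario_config(4)
  rep4 <- run_scenario(cfg4, long, terms, B = B, seed = seed)
  cfg3 <- scenario_config(3)
  rep3 <- run_scenario(cfg3, long, terms, B = B, seed = seed)
  pars <- rep4$vgm_params
  truth_a0 <- dat$truth$variogram_schedule$a0[pars$day]
  rel_err <- abs(pars$a0 - truth_a0) / truth_a0
  winter <- pars$day <= 60 | pars$day > 330
  summer <- pars$day > 150 & pars$day <= 240
  list(oob_r2 = rep3$r2, kriged_r2 = rep4$r2,
       attainable_r2 = dat$truth$attainable_r2_log,
       field_variance_fraction = dat$truth$field_variance_fraction,
       a0_median_rel_error = median(rel_err[pars$kriged], na.rm = TRUE),
       winter_median_a0 = median(pars$a0[pars$kriged & winter], na.rm = TRUE),
       summer_median_a0 = median(pars$a0[pars$kriged & summer], na.rm = TRUE),
       vgm_params = pars,
       basis_variance_fraction = basis$variance_fraction)
}
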