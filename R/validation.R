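# Model-comparison scenarios, k-fold cross-validation, out-of-bag validation
# and accuracy metrics. Six scenarios cross the engine (single additive model
# vs bagged ensemble), the use of co-located PM10 as a predictor, and the use
# of daily residual kriging.

#' Accuracy metrics on paired observed/predicted values
#'
#' R2 = 1 - SSE/SST (fraction of variance explained; can be negative for a
#' predictor worse than the mean) and RMSE on whatever scale the inputs carry.
#'
#' @param observed,predicted equal-length numeric vectors; pairs with either
#'   value missing are dropped (at least 2 must remain).
#' @return list with `r2`, `rmse`, `n`. `r2` is NA (flagged) when the observed
#'   values are constant.
#' @export
metrics <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted))
  ok <- !is.na(observed) & !is.na(predicted)
  o <- observed[ok]; p <- predicted[ok]
  if (length(o) < 2) stop("need at least 2 non-missing pairs")
  sst <- sum((o - mean(o))^2)
  rmse <- sqrt(mean((o - p)^2))
  r2 <- if (sst > 0) 1 - sum((o - p)^2) / sst else NA_real_
  list(r2 = r2, rmse = rmse, n = length(o))
}

#' Scenario configuration (Table-2-style model grid)
#'
#' 1: single additive model, no PM10, no kriging; 2: single model + PM10;
#' 3: bagging; 4: bagging + residual kriging; 5: bagging + PM10;
#' 6: bagging + PM10 + residual kriging.
#'
#' @param id scenario id in 1..6.
#' @return list(id, engine, use_pm10, use_residual_kriging).
#' @export
scenario_config <- function(id) {
  stopifnot(id %in% 1:6)
  grid <- list(
    list(engine = "single_gam", use_pm10 = FALSE, use_residual_kriging = FALSE),
    list(engine = "single_gam", use_pm10 = TRUE,  use_residual_kriging = FALSE),
    list(engine = "bagging",    use_pm10 = FALSE, use_residual_kriging = FALSE),
    list(engine = "bagging",    use_pm10 = FALSE, use_residual_kriging = TRUE),
    list(engine = "bagging",    use_pm10 = TRUE,  use_residual_kriging = FALSE),
    list(engine = "bagging",    use_pm10 = TRUE,  use_residual_kriging = TRUE)
  )
  c(list(id = id), grid[[id]])
}

#' Repeated k-fold cross-validation of a single additive model
#'
#' Fold assignment is record-level by default (each station-day is a record),
#' repeated `repeats` times with independent partitions; metrics are pooled
#' over folds within each repeat and computed on back-transformed
#' concentrations. A station-level assignment (`stratify_by_station = TRUE`
#' holds out whole stations) is available for spatial validation.
#'
#' @param data modelling table with `log_pm25`.
#' @param smooth_terms,wind_pair,linear_terms,max_df model specification
#'   passed to [fit_additive()].
#' @param k folds (>= 2, <= number of records/stations).
#' @param repeats independent repetitions.
#' @param seed RNG seed.
#' @param stratify_by_station assign folds by station instead of record.
#' @return list: pooled `r2`/`rmse` (means over repeats), `per_repeat`
#'   data.frame, `k`, `repeats`.
#' @export
kfold_cv <- function(data, smooth_terms, wind_pair = NULL,
                     linear_terms = character(0), max_df = 10,
                     k = 10, repeats = 10, seed = 1,
                     stratify_by_station = FALSE) {
  stopifnot(k >= 2)
  n <- nrow(data)
  if (k > n) stop("k exceeds the number of records")
  set.seed(seed)
  per_repeat <- data.frame(repeat_ = seq_len(repeats), r2 = NA_real_,
                           rmse = NA_real_)
  for (r in seq_len(repeats)) {
    if (stratify_by_station) {
      st <- unique(data$station_id)
      if (k > length(st)) stop("k exceeds the number of stations")
      st_fold <- sample(rep(seq_len(k), length.out = length(st)))
      fold <- st_fold[match(data$station_id, st)]
    } else {
      fold <- sample(rep(seq_len(k), length.out = n))
    }
    pred_log <- rep(NA_real_, n)
    for (f in seq_len(k)) {
      test <- fold == f
      fit <- fit_additive(data[!test, , drop = FALSE], "log_pm25",
                          smooth_terms, wind_pair, linear_terms, max_df)
      pred_log[test] <- predict(fit, data[test, , drop = FALSE])
    }
    m <- metrics(exp(data$log_pm25), exp(pred_log))
    per_repeat$r2[r] <- m$r2
    per_repeat$rmse[r] <- m$rmse
  }
  list(r2 = mean(per_repeat$r2), rmse = mean(per_repeat$rmse),
       r2_sd = sd(per_repeat$r2), per_repeat = per_repeat,
       k = k, repeats = repeats)
}

#' Run one model scenario and report held-out accuracy
#'
#' Single-model scenarios (1-2) are validated by repeated k-fold
#' cross-validation; bagging scenarios (3-6) by out-of-bag prediction (each
#' record predicted only by members that did not train on it). When residual
#' kriging is on, each station-day's out-of-bag residual is estimated by
#' leave-one-station-out ordinary kriging within its day (the station's own
#' residual never informs its evaluated prediction) and added to the log-scale
#' prediction. Metrics are computed on back-transformed concentrations.
#'
#' @param config a [scenario_config()].
#' @param data modelling table (columns `station_id`, `day`, `x`, `y`,
#'   `log_pm25`, `log_pm10` when needed, plus covariates).
#' @param covariate_terms covariate column names entering as smooths
#'   (`log_pm10` is appended automatically when the scenario uses PM10).
#' @param wind_pair optional bivariate wind smooth, passed through.
#' @param B ensemble size for bagging scenarios.
#' @param seed RNG seed.
#' @param cv_k,cv_repeats k-fold settings for single-model scenarios.
#' @param vgm_family variogram family for residual kriging (`"select"` for
#'   per-day LOOCV family selection).
#' @param min_stations minimum stations per day for kriging (else that day's
#'   residual term is 0, with a warning at the end).
#' @param max_df smooth basis cap.
#' @return list of class `pm_metric_report`: `scenario`, `r2`, `rmse`, `n`,
#'   plus engine-specific detail (`per_repeat` or `oob`, `vgm_params`).
#' @export
run_scenario <- function(config, data, covariate_terms, wind_pair = NULL,
                         B = 25, seed = 1, cv_k = 10, cv_repeats = 10,
                         vgm_family = "exponential", min_stations = 10,
                         max_df = 10) {
  stopifnot(is.list(config), all(c("engine", "use_pm10", "use_residual_kriging")
                                 %in% names(config)))
  terms <- covariate_terms
  if (isTRUE(config$use_pm10)) {
    if (!"log_pm10" %in% names(data)) stop("scenario needs a log_pm10 column")
    terms <- c("log_pm10", terms)
  }
  keep <- complete.cases(data[, c("log_pm25", terms), drop = FALSE])
  data <- data[keep, , drop = FALSE]
  if (config$engine == "single_gam") {
    cv <- kfold_cv(data, terms, wind_pair, max_df = max_df,
                   k = cv_k, repeats = cv_repeats, seed = seed)
    out <- list(scenario = config$id, engine = "single_gam",
                r2 = cv$r2, rmse = cv$rmse, n = nrow(data),
                per_repeat = cv$per_repeat)
    class(out) <- "pm_metric_report"
    return(out)
  }
  ens <- bagging_fit(data, "log_pm25", terms, wind_pair, max_df = max_df,
                     B = B, seed = seed)
  oob <- oob_ensemble_predictions(ens, data)
  pred_log <- oob$mean_log
  vgm_params <- NULL
  if (isTRUE(config$use_residual_kriging)) {
    kr <- oob_residual_kriging(data, pred_log, vgm_family = vgm_family,
                               min_stations = min_stations)
    pred_log <- pred_log + kr$residual_log
    vgm_params <- kr$params
  }
  m <- metrics(exp(data$log_pm25), exp(pred_log))
  out <- list(scenario = config$id, engine = "bagging", r2 = m$r2,
              rmse = m$rmse, n = m$n, oob_r2_members = ens$oob_r2,
              weights = ens$weights, vgm_params = vgm_params,
              predictions = data.frame(station_id = data$station_id,
                                       day = data$day, pred_log = pred_log,
                                       obs_log = data$log_pm25))
  class(out) <- "pm_metric_report"
  out
}

#' @export
print.pm_metric_report <- function(x, ...) {
  cat(sprintf("<pm_metric_report> scenario %s (%s): R2 = %.3f, RMSE = %.2f ug/m3 (n = %d)\n",
              x$scenario, x$engine, x$r2, x$rmse, x$n))
  invisible(x)
}

# Per-day leave-one-station-out kriging of out-of-bag residuals; returns the
# kriged residual per row (0 on days without kriging) and the per-day
# variogram parameter table.
oob_residual_kriging <- function(data, pred_log, vgm_family = "exponential",
                                 min_stations = 10) {
  resid <- data$log_pm25 - pred_log
  days <- sort(unique(data$day))
  residual_log <- rep(0, nrow(data))
  params <- data.frame(day = days, kriged = FALSE, family = NA_character_,
                       nugget = NA_real_, partial_sill = NA_real_,
                       a0 = NA_real_, effective_range = NA_real_,
                       stringsAsFactors = FALSE)
  skipped <- 0L
  for (di in seq_along(days)) {
    rows <- which(data$day == days[di] & !is.na(resid))
    if (length(rows) < min_stations) {
      skipped <- skipped + 1L
      next
    }
    loc <- data.frame(x = data$x[rows], y = data$y[rows])
    res <- resid[rows]
    vgm <- tryCatch(suppressWarnings({
      emp <- empirical_variogram(res, loc)
      if (identical(vgm_family, "select")) {
        select_family_loocv(res, loc, emp = emp)
      } else {
        fit_day_variogram(res, loc, vgm_family, emp = emp, day = days[di])
      }
    }), error = function(e) NULL)
    if (is.null(vgm) || (vgm$c0 == 0 && vgm$c == 0)) next
    cv <- tryCatch(loocv_krige(res, loc, vgm), error = function(e) NULL)
    if (is.null(cv)) next
    residual_log[rows] <- cv$predicted
    params$kriged[di] <- TRUE
    params$family[di] <- vgm$family
    params$nugget[di] <- vgm$c0
    params$partial_sill[di] <- vgm$c
    # range is undefined for a pure-nugget day
    params$a0[di] <- if (vgm$c > 0) vgm$a0 else NA_real_
    params$effective_range[di] <- if (vgm$c > 0) vgm$effective_range else NA_real_
  }
  if (skipped > 0) {
    warning(skipped, " day(s) below the ", min_stations,
            "-station threshold: residual term set to 0 (no kriging)")
  }
  list(residual_log = residual_log, params = params)
}

#' Compare several scenarios on one dataset
#'
#' @param ids scenario ids to run.
#' @inheritParams run_scenario
#' @return data.frame (scenario, engine, use_pm10, use_residual_kriging, r2,
#'   rmse) — one row per scenario, Table-2 shaped.
#' @export
compare_scenarios <- function(ids, data, covariate_terms, wind_pair = NULL,
                              B = 25, seed = 1, cv_k = 10, cv_repeats = 10,
                              vgm_family = "exponential", min_stations = 10,
                              max_df = 10) {
  rows <- lapply(ids, function(id) {
    cfg <- scenario_config(id)
    rep <- run_scenario(cfg, data, covariate_terms, wind_pair, B, seed,
                        cv_k, cv_repeats, vgm_family, min_stations, max_df)
    data.frame(scenario = id, engine = cfg$engine, use_pm10 = cfg$use_pm10,
               use_residual_kriging = cfg$use_residual_kriging,
               r2 = rep$r2, rmse = rep$rmse)
  })
  do.call(rbind, rows)
}
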