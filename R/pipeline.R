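# High-level orchestration: fit the full estimation pipeline on panels and
# produce location/day predictions with uncertainty and optional kriged
# residual terms.

#' Fit the full estimation pipeline
#'
#' Imputes the PM2.5 panel by truncated SVD, extracts and smooths the two
#' temporal basis functions, flattens panels and covariates to a modelling
#' table, and fits the bagged additive ensemble. When residual kriging is
#' enabled the ensemble's (full-data) station residuals are stored per day so
#' surfaces can be kriged at prediction time.
#'
#' @param pm25,pm10 concentration-scale `pm_panel`s (`pm10` optional; required
#'   when `use_pm10`).
#' @param covariates a [covariate_table()].
#' @param covariate_terms covariate columns entering as smooths.
#' @param use_pm10 include log PM10 as a predictor.
#' @param use_residual_kriging store per-day station residuals for kriging.
#' @param B ensemble size.
#' @param seed RNG seed.
#' @param smoothing_df spline df for the temporal basis.
#' @param max_df smooth basis cap in the additive fits.
#' @return object of class `pm_pipeline`: `ensemble`, `basis`, `stations`,
#'   `residuals` (stations x days matrix of log-scale residuals or NULL),
#'   `terms`, `long` (the modelling table).
#' @export
fit_pipeline <- function(pm25, pm10 = NULL, covariates = NULL,
                         covariate_terms = character(0), use_pm10 = FALSE,
                         use_residual_kriging = TRUE, B = 25, seed = 1,
                         smoothing_df = 12, max_df = 10) {
  if (use_pm10 && is.null(pm10)) stop("use_pm10 = TRUE but no PM10 panel given")
  imp <- svd_impute(log_transform(pm25))
  basis <- smooth_basis(extract_basis(imp), smoothing_df)
  long <- panel_to_long(pm25, covariates, basis, pm10)
  terms <- c("f1", "f2", covariate_terms)
  if (use_pm10) terms <- c("log_pm10", terms)
  keep <- complete.cases(long[, c("log_pm25", terms), drop = FALSE])
  long <- long[keep, , drop = FALSE]
  ens <- bagging_fit(long, "log_pm25", terms, max_df = max_df, B = B,
                     seed = seed)
  residuals <- NULL
  if (use_residual_kriging) {
    pred <- predict(ens, long)$mean_log
    res <- long$log_pm25 - pred
    days <- sort(unique(long$day))
    residuals <- matrix(NA_real_, nrow(pm25$stations), length(days),
                        dimnames = list(pm25$stations$id, days))
    residuals[cbind(match(long$station_id, pm25$stations$id),
                    match(long$day, days))] <- res
  }
  structure(list(ensemble = ens, basis = basis, stations = pm25$stations,
                 residuals = residuals, terms = terms, long = long,
                 seed = seed),
            class = "pm_pipeline")
}

#' Predict concentrations at locations and days
#'
#' Ensemble members predict the log concentration for each requested row; the
#' weighted mean and SD come from the ensemble, and (when the pipeline stores
#' residuals) a kriged daily residual term is added before back-transforming:
#' concentration = exp(mean_log + residual_log).
#'
#' @param pipeline a fitted `pm_pipeline`.
#' @param newdata data.frame with `x`, `y`, `day` and every covariate the
#'   ensemble terms need (`f1`/`f2` filled from the basis when absent).
#' @param krige_residuals add the kriged residual term (requires stored
#'   residuals).
#' @param vgm_family variogram family for the daily fits.
#' @param min_stations station threshold per day below which the residual
#'   term is 0.
#' @return data.frame: x, y, day, mean_log, sd_log, residual_log,
#'   concentration.
#' @export
predict_locations <- function(pipeline, newdata, krige_residuals = TRUE,
                              vgm_family = "exponential", min_stations = 10) {
  stopifnot(inherits(pipeline, "pm_pipeline"))
  newdata <- as.data.frame(newdata)
  stopifnot(all(c("x", "y", "day") %in% names(newdata)))
  if (!"f1" %in% names(newdata)) {
    j <- match(newdata$day, pipeline$basis$days)
    newdata$f1 <- pipeline$basis$f1[j]
    newdata$f2 <- pipeline$basis$f2[j]
  }
  ep <- predict(pipeline$ensemble, newdata)
  residual_log <- rep(0, nrow(newdata))
  if (krige_residuals) {
    if (is.null(pipeline$residuals)) {
      stop("pipeline was fitted without residual kriging")
    }
    loc <- pipeline$stations[, c("x", "y")]
    day_cols <- as.integer(colnames(pipeline$residuals))
    for (d in unique(newdata$day)) {
      ci <- match(d, day_cols)
      if (is.na(ci)) next
      res <- pipeline$residuals[, ci]
      if (sum(!is.na(res)) < min_stations) next
      vgm <- tryCatch(suppressWarnings({
        emp <- empirical_variogram(res, loc)
        if (identical(vgm_family, "select")) {
          select_family_loocv(res, loc, emp = emp)
        } else {
          fit_day_variogram(res, loc, vgm_family, emp = emp, day = d)
        }
      }), error = function(e) NULL)
      if (is.null(vgm) || (vgm$c0 == 0 && vgm$c == 0)) next
      rows <- which(newdata$day == d)
      residual_log[rows] <- krige(res, loc, vgm,
                                  newdata[rows, c("x", "y")])$estimate
    }
  }
  data.frame(x = newdata$x, y = newdata$y, day = newdata$day,
             mean_log = ep$mean_log, sd_log = ep$sd_log,
             residual_log = residual_log,
             concentration = exp(ep$mean_log + residual_log))
}
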