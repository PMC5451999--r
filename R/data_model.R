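#' @importFrom stats aggregate coef complete.cases cor dist fitted lm median
#'   optim predict quantile rexp rnorm runif sd setNames smooth.spline var AIC
#' @importFrom utils read.csv write.csv head
NULL

# -- planar projection --------------------------------------------------------

#' Project longitude/latitude to planar metres
#'
#' Deterministic local projection centred on a reference point (by default the
#' centre of the coordinate bounding box): an equirectangular projection on the
#' WGS84 mean Earth radius, adequate for provincial extents where variogram and
#' kriging distances must be metric. The same origin must be reused when
#' projecting prediction targets.
#'
#' @param lon,lat numeric vectors, WGS84 decimal degrees.
#' @param origin optional `c(lon0, lat0)`; defaults to the bbox centre.
#' @return data.frame with columns `x`, `y` in metres, plus the origin as the
#'   `"origin"` attribute.
#' @export
project_lonlat <- function(lon, lat, origin = NULL) {
  stopifnot(length(lon) == length(lat), all(is.finite(lon)), all(is.finite(lat)))
  if (is.null(origin)) {
    origin <- c(mean(range(lon)), mean(range(lat)))
  }
  R <- 6371008.8  # mean Earth radius, metres
  d2r <- pi / 180
  out <- data.frame(
    x = R * (lon - origin[1]) * d2r * cos(origin[2] * d2r),
    y = R * (lat - origin[2]) * d2r
  )
  attr(out, "origin") <- origin
  out
}

#' Inverse of [project_lonlat()]
#' @param x,y planar coordinates in metres.
#' @param origin `c(lon0, lat0)` used for the forward projection.
#' @return data.frame with columns `lon`, `lat`.
#' @export
unproject_xy <- function(x, y, origin) {
  R <- 6371008.8
  d2r <- pi / 180
  data.frame(
    lon = origin[1] + x / (R * cos(origin[2] * d2r)) / d2r,
    lat = origin[2] + y / R / d2r
  )
}

# -- measurement panel --------------------------------------------------------

#' Construct a station-by-day measurement panel
#'
#' The panel is the central container: a stations x days matrix of daily mean
#' concentrations (ug/m3) with NA as the explicit missing marker, plus the
#' station table (id, lon/lat and projected x/y in metres).
#'
#' @param stations data.frame with columns `id`, `lon`, `lat` (and optionally
#'   `x`, `y`; computed by projection when absent).
#' @param days integer vector of 1-based day-of-year indices, strictly
#'   increasing.
#' @param values numeric matrix, `nrow(stations)` x `length(days)`; all
#'   non-missing entries must be positive concentrations.
#' @param pollutant `"PM25"` or `"PM10"`.
#' @param origin optional projection origin passed to [project_lonlat()].
#' @return object of class `pm_panel`.
#' @export
pm_panel <- function(stations, days, values, pollutant = c("PM25", "PM10"),
                     origin = NULL) {
  pollutant <- match.arg(pollutant)
  stations <- as.data.frame(stations)
  stopifnot(all(c("id", "lon", "lat") %in% names(stations)))
  stations$id <- as.character(stations$id)
  if (anyDuplicated(stations$id)) {
    stop("duplicate station ids: ",
         paste(unique(stations$id[duplicated(stations$id)]), collapse = ", "))
  }
  days <- as.integer(days)
  if (is.unsorted(days, strictly = TRUE)) stop("'days' must be strictly increasing")
  values <- as.matrix(values)
  if (nrow(values) != nrow(stations) || ncol(values) != length(days)) {
    stop("values matrix must be n_stations x n_days (",
         nrow(stations), " x ", length(days), ")")
  }
  bad <- which(!is.na(values) & values <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("nonpositive concentration at station '%s', day %d",
                 stations$id[bad[1, 1]], days[bad[1, 2]]))
  }
  if (!all(c("x", "y") %in% names(stations))) {
    pr <- project_lonlat(stations$lon, stations$lat, origin)
    stations$x <- pr$x
    stations$y <- pr$y
    origin <- attr(pr, "origin")
  }
  dimnames(values) <- list(stations$id, days)
  structure(
    list(stations = stations, days = days, values = values,
         pollutant = pollutant, origin = origin, log_scale = FALSE),
    class = "pm_panel"
  )
}

#' @export
print.pm_panel <- function(x, ...) {
  cat(sprintf("<pm_panel> %s: %d stations x %d days, %.1f%% missing%s\n",
              x$pollutant, nrow(x$values), ncol(x$values),
              100 * missing_fraction(x),
              if (x$log_scale) " (log scale)" else ""))
  invisible(x)
}

#' @export
dim.pm_panel <- function(x) dim(x$values)

#' Fraction of missing entries in a panel
#' @param panel a `pm_panel`.
#' @return scalar in \[0, 1\].
#' @export
missing_fraction <- function(panel) {
  stopifnot(inherits(panel, "pm_panel"))
  mean(is.na(panel$values))
}

# -- daily aggregation --------------------------------------------------------

#' Daily mean from hourly values under a coverage rule
#'
#' Hourly monitoring records are aggregated to a daily mean only when enough of
#' the 24-hour period was observed (the 75% measurement standard by default):
#' the mean of the present values is returned when present-count/24 >= coverage,
#' otherwise NA.
#'
#' @param hourly numeric vector of at most 24 values, NA marking missing hours.
#' @param coverage required fraction of the 24-hour day, in (0, 1\].
#' @return daily mean, or NA when coverage is not met.
#' @export
daily_average <- function(hourly, coverage = 0.75) {
  stopifnot(is.numeric(coverage), length(coverage) == 1,
            coverage > 0, coverage <= 1)
  if (length(hourly) > 24) stop("more than 24 hourly values supplied")
  if (length(hourly) == 0) return(NA_real_)
  present <- hourly[!is.na(hourly)]
  if (any(present < 0)) stop("negative hourly concentrations are invalid")
  if (length(present) / 24 >= coverage) mean(present) else NA_real_
}

# -- log transforms -----------------------------------------------------------

#' Natural-log transform of a panel
#'
#' Concentrations are modelled on the natural-log scale; back-transform is
#' naive exponentiation with no bias-correction factor.
#'
#' @param panel a `pm_panel` on the concentration scale.
#' @return the panel with values replaced by their natural logs.
#' @export
log_transform <- function(panel) {
  stopifnot(inherits(panel, "pm_panel"))
  if (panel$log_scale) stop("panel is already on the log scale")
  bad <- which(!is.na(panel$values) & panel$values <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("nonpositive value at station '%s', day %s",
                 rownames(panel$values)[bad[1, 1]],
                 colnames(panel$values)[bad[1, 2]]))
  }
  panel$values <- log(panel$values)
  panel$log_scale <- TRUE
  panel
}

#' Back-transform log-scale values to concentrations
#' @param x numeric vector/matrix of log concentrations, or a log-scale
#'   `pm_panel`.
#' @return concentrations in ug/m3 (same shape / a concentration-scale panel).
#' @export
back_transform <- function(x) {
  if (inherits(x, "pm_panel")) {
    if (!x$log_scale) stop("panel is not on the log scale")
    x$values <- exp(x$values)
    x$log_scale <- FALSE
    return(x)
  }
  exp(x)
}

# -- I/O ----------------------------------------------------------------------

#' Read a long-format measurement CSV into a panel
#'
#' Expected columns: `station_id`, `lon`, `lat`, `date` (ISO or day-of-year
#' integer), `value` (ug/m3). Stations are ordered by id and days ascending,
#' so reading is deterministic. Duplicate (station, date) rows are an error.
#'
#' @param path CSV file path.
#' @param pollutant `"PM25"` or `"PM10"`.
#' @param origin optional projection origin.
#' @return a `pm_panel`.
#' @export
read_panel <- function(path, pollutant = c("PM25", "PM10"), origin = NULL) {
  pollutant <- match.arg(pollutant)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("station_id", "lon", "lat", "date", "value")
  if (!all(need %in% names(df))) {
    stop("missing required columns: ", paste(setdiff(need, names(df)), collapse = ", "))
  }
  day <- parse_day(df$date)
  key <- paste(df$station_id, day)
  if (anyDuplicated(key)) {
    stop("duplicate (station, date) rows for key(s): ",
         paste(head(unique(key[duplicated(key)]), 3), collapse = "; "))
  }
  st <- unique(df[, c("station_id", "lon", "lat")])
  st <- st[order(st$station_id), ]
  if (anyDuplicated(st$station_id)) {
    stop("station id with inconsistent coordinates: ",
         st$station_id[duplicated(st$station_id)][1])
  }
  days <- sort(unique(day))
  values <- matrix(NA_real_, nrow(st), length(days))
  i <- match(df$station_id, st$station_id)
  j <- match(day, days)
  values[cbind(i, j)] <- df$value
  pm_panel(data.frame(id = st$station_id, lon = st$lon, lat = st$lat),
           days, values, pollutant, origin)
}

parse_day <- function(date) {
  if (is.numeric(date)) return(as.integer(date))
  suppressWarnings(num <- as.integer(date))
  if (!anyNA(num)) return(num)
  d <- as.Date(date, format = "%Y-%m-%d")
  if (anyNA(d)) {
    stop("unparseable date at row ", which(is.na(d))[1], ": '",
         date[which(is.na(d))[1]], "'")
  }
  as.integer(strftime(d, "%j"))
}

#' Write a panel to long-format CSV
#'
#' Inverse of [read_panel()]: one row per non-missing (station, day) entry,
#' stations by id and days ascending, so write-then-read round-trips.
#'
#' @param panel a `pm_panel` on the concentration scale.
#' @param path output CSV path.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "pm_panel"))
  if (panel$log_scale) stop("write concentration-scale panels only")
  idx <- which(!is.na(panel$values), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  out <- data.frame(
    station_id = panel$stations$id[idx[, 1]],
    lon = panel$stations$lon[idx[, 1]],
    lat = panel$stations$lat[idx[, 1]],
    date = panel$days[idx[, 2]],
    value = panel$values[idx]
  )
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write prediction results to CSV
#'
#' @param results data.frame with columns `x`, `y`, `day`, `mean_log`,
#'   `sd_log`, `residual_log`, `concentration` (as produced by
#'   [predict_locations()]).
#' @param path output CSV path.
#' @export
write_predictions <- function(results, path) {
  need <- c("x", "y", "day", "mean_log", "sd_log", "residual_log", "concentration")
  if (!all(need %in% names(results))) {
    stop("missing prediction columns: ",
         paste(setdiff(need, names(results)), collapse = ", "))
  }
  write.csv(results[, need], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# -- long format for modelling ------------------------------------------------

#' Flatten panel + covariates into a modelling table
#'
#' One row per non-missing (station, day): response `log_pm25`, coordinates in
#' km, any spatial covariates (recycled across days) and spatiotemporal
#' covariates (matched by station and day), plus optional log PM10 and the
#' temporal basis functions `f1`, `f2`.
#'
#' @param panel PM2.5 `pm_panel` (concentration scale).
#' @param covariates optional [covariate_table()].
#' @param basis optional `pm_temporal_basis` whose smoothed `f1`, `f2` are
#'   joined by day.
#' @param pm10 optional PM10 `pm_panel` aligned with `panel`; adds `log_pm10`.
#' @return data.frame with one row per observed station-day.
#' @export
panel_to_long <- function(panel, covariates = NULL, basis = NULL, pm10 = NULL) {
  stopifnot(inherits(panel, "pm_panel"), !panel$log_scale)
  idx <- which(!is.na(panel$values), arr.ind = TRUE)
  idx <- idx[order(idx[, 2], idx[, 1]), , drop = FALSE]
  df <- data.frame(
    station_id = panel$stations$id[idx[, 1]],
    day = panel$days[idx[, 2]],
    x = panel$stations$x[idx[, 1]],
    y = panel$stations$y[idx[, 1]],
    log_pm25 = log(panel$values[idx]),
    stringsAsFactors = FALSE
  )
  if (!is.null(pm10)) {
    stopifnot(inherits(pm10, "pm_panel"), !pm10$log_scale)
    i <- match(df$station_id, pm10$stations$id)
    j <- match(df$day, pm10$days)
    v <- pm10$values[cbind(i, j)]
    df$log_pm10 <- ifelse(!is.na(v) & v > 0, log(v), NA_real_)
  }
  if (!is.null(basis)) {
    j <- match(df$day, basis$days)
    df$f1 <- basis$f1[j]
    df$f2 <- basis$f2[j]
  }
  if (!is.null(covariates)) {
    if (!is.null(covariates$spatial)) {
      i <- match(df$station_id, covariates$spatial$station_id)
      for (nm in setdiff(names(covariates$spatial), "station_id")) {
        df[[nm]] <- covariates$spatial[[nm]][i]
      }
    }
    if (!is.null(covariates$spatiotemporal)) {
      stkey <- paste(covariates$spatiotemporal$station_id,
                     covariates$spatiotemporal$day)
      i <- match(paste(df$station_id, df$day), stkey)
      for (nm in setdiff(names(covariates$spatiotemporal), c("station_id", "day"))) {
        df[[nm]] <- covariates$spatiotemporal[[nm]][i]
      }
    }
  }
  df
}

#' Bundle spatial and spatiotemporal covariates
#'
#' @param spatial data.frame keyed by `station_id` (one row per station).
#' @param spatiotemporal data.frame keyed by (`station_id`, `day`).
#' @param units optional named character vector of per-column units.
#' @return object of class `covariate_table`.
#' @export
covariate_table <- function(spatial = NULL, spatiotemporal = NULL, units = NULL) {
  if (!is.null(spatial)) {
    stopifnot("station_id" %in% names(spatial))
    spatial$station_id <- as.character(spatial$station_id)
  }
  if (!is.null(spatiotemporal)) {
    stopifnot(all(c("station_id", "day") %in% names(spatiotemporal)))
    spatiotemporal$station_id <- as.character(spatiotemporal$station_id)
  }
  structure(list(spatial = spatial, spatiotemporal = spatiotemporal,
                 units = units),
            class = "covariate_table")
}
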