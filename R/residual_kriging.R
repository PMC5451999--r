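# Daily geostatistics of ensemble residuals: empirical semivariograms,
# weighted-least-squares fitting of parametric variogram families, family
# selection by leave-one-station-out cross-validation, and ordinary kriging
# with the unbiasedness constraint. All distances are planar metres.

VGM_FAMILIES <- c("exponential", "spherical", "circular", "gaussian", "linear")

#' Evaluate a parametric variogram
#'
#' gamma(0) = 0 by definition; for d > 0 the bounded families rise from the
#' nugget c0 towards the sill c0 + c with range parameter a0. The exponential
#' family is gamma(d) = c0 + c (1 - exp(-d / a0)) with effective range ~3 a0.
#' The linear family is unbounded: gamma(d) = c0 + c d / a0.
#'
#' @param d distances (metres), vectorized.
#' @param family one of `r paste(VGM_FAMILIES, collapse = ", ")`.
#' @param c0 nugget (>= 0).
#' @param c partial sill (>= 0).
#' @param a0 range parameter (> 0).
#' @return semivariance values.
#' @export
variogram_value <- function(d, family, c0, c, a0) {
  family <- match.arg(family, VGM_FAMILIES)
  stopifnot(c0 >= 0, c >= 0, a0 > 0)
  h <- d / a0
  g <- switch(family,
    exponential = c0 + c * (1 - exp(-h)),
    gaussian    = c0 + c * (1 - exp(-h^2)),
    spherical   = ifelse(h < 1, c0 + c * (1.5 * h - 0.5 * h^3), c0 + c),
    circular    = {
      hh <- pmin(h, 1)
      ifelse(h < 1,
             c0 + c * (1 - (2 / pi) * (acos(hh) - hh * sqrt(pmax(0, 1 - hh^2)))),
             c0 + c)
    },
    linear      = c0 + c * h
  )
  g[d == 0] <- 0
  g
}

#' Construct a fitted variogram model object
#' @param family variogram family name.
#' @param c0,c,a0 nugget, partial sill, range parameter.
#' @param day optional day index the model belongs to.
#' @param diagnostics optional list (weighted SSE, LOOCV RMSE, ...).
#' @return object of class `pm_variogram`.
#' @export
variogram_model <- function(family, c0, c, a0, day = NA_integer_,
                            diagnostics = list()) {
  family <- match.arg(family, VGM_FAMILIES)
  stopifnot(c0 >= 0, c >= 0, a0 > 0)
  structure(list(family = family, c0 = c0, c = c, a0 = a0, day = day,
                 effective_range = if (family == "exponential") 3 * a0 else a0,
                 diagnostics = diagnostics),
            class = "pm_variogram")
}

#' @export
print.pm_variogram <- function(x, ...) {
  cat(sprintf("<pm_variogram> %s: nugget %.4g, partial sill %.4g, a0 %.4g m\n",
              x$family, x$c0, x$c, x$a0))
  invisible(x)
}

#' Empirical semivariogram of one day's residuals
#'
#' Pairs are binned by separation distance into `n_bins` equal-width lag bins
#' up to `max_lag` (default half the maximum inter-station distance); each
#' bin's semivariance is half the mean squared residual difference over its
#' pairs. Bins with fewer than `min_pairs` pairs are dropped.
#'
#' @param residuals numeric vector of residuals (one per station; NAs dropped
#'   with their locations).
#' @param locations matrix/data.frame of planar x, y (metres).
#' @param n_bins number of lag bins.
#' @param max_lag maximum pair separation considered (metres).
#' @param min_pairs minimum pairs per retained bin.
#' @return object of class `pm_empirical_variogram`: `dist` (mean pair
#'   distance per bin), `gamma`, `np` (pair counts), `max_lag`, `n_used`.
#' @export
empirical_variogram <- function(residuals, locations, n_bins = 12,
                                max_lag = NULL, min_pairs = 5) {
  locations <- as.matrix(as.data.frame(locations)[, c("x", "y")])
  keep <- !is.na(residuals)
  residuals <- residuals[keep]
  locations <- locations[keep, , drop = FALSE]
  n <- length(residuals)
  if (n < 2) stop("need at least 2 non-missing residuals")
  D <- as.matrix(dist(locations))
  if (is.null(max_lag)) max_lag <- max(D) / 2
  iu <- which(upper.tri(D), arr.ind = TRUE)
  d <- D[iu]
  g <- 0.5 * (residuals[iu[, 1]] - residuals[iu[, 2]])^2
  ok <- d > 0 & d <= max_lag
  d <- d[ok]; g <- g[ok]
  if (length(d) == 0) stop("no station pairs within max_lag")
  breaks <- seq(0, max_lag, length.out = n_bins + 1)
  bin <- cut(d, breaks, include.lowest = FALSE, labels = FALSE)
  np <- tabulate(bin, nbins = n_bins)
  gamma_hat <- vapply(seq_len(n_bins),
                      function(b) if (np[b] > 0) mean(g[bin == b]) else NA_real_,
                      numeric(1))
  dist_mean <- vapply(seq_len(n_bins),
                      function(b) if (np[b] > 0) mean(d[bin == b]) else NA_real_,
                      numeric(1))
  keep_bin <- np >= min_pairs
  structure(list(dist = dist_mean[keep_bin], gamma = gamma_hat[keep_bin],
                 np = np[keep_bin], max_lag = max_lag, n_bins = n_bins,
                 n_used = n),
            class = "pm_empirical_variogram")
}

#' Fit a variogram family to an empirical variogram
#'
#' Parameters minimize the pair-count-weighted sum of squared differences
#' between the model and the empirical semivariances (Cressie weights
#' np/gamma^2 available as an option), subject to c0 >= 0, c >= 0, a0 > 0.
#' Optimization is multi-start (deterministic a0 grid) L-BFGS-B; if every
#' start fails a pure-nugget model is returned with a warning.
#'
#' A structured fit is only kept when it beats the pure-nugget model by an
#' F-style parsimony criterion on the weighted SSE (the structured families
#' contain a degenerate ridge — a vanishing range mimics a nugget — so on
#' spatially independent residuals an unguarded WLS reports spurious
#' structure). Set `parsimony = FALSE` to disable.
#'
#' @param emp a `pm_empirical_variogram` with at least 4 retained bins (2 for
#'   the linear family).
#' @param family variogram family to fit.
#' @param weights `"np"` (pair counts) or `"cressie"`.
#' @param day day index stored on the result.
#' @param parsimony keep the structured model only if it clears the F-style
#'   improvement threshold (level 0.95) over pure nugget.
#' @return a `pm_variogram` with weighted SSE in `diagnostics$wsse`.
#' @export
fit_variogram <- function(emp, family = "exponential",
                          weights = c("np", "cressie"), day = NA_integer_,
                          parsimony = TRUE) {
  stopifnot(inherits(emp, "pm_empirical_variogram"))
  family <- match.arg(family, VGM_FAMILIES)
  weights <- match.arg(weights)
  d <- emp$dist; g <- emp$gamma; np <- emp$np
  if (length(d) < 4 && family != "linear") stop("need >= 4 retained lag bins")
  if (length(d) < 2) stop("need >= 2 retained lag bins")
  if (all(g == 0)) {
    warning("all semivariances are zero; returning zero variogram")
    return(variogram_model(family, 0, 0, emp$max_lag, day,
                           diagnostics = list(wsse = 0, degenerate = TRUE)))
  }
  gmax <- max(g)
  obj <- function(par) {
    gm <- variogram_value(d, family, par[1], par[2], par[3])
    w <- if (weights == "np") np else np / pmax(gm, 1e-10 * gmax)^2
    sum(w * (g - gm)^2)
  }
  if (family == "linear") {
    # slope parameterized as c / a0 with a0 pinned at max_lag
    a0_fix <- emp$max_lag
    obj2 <- function(par) obj(c(par[1], par[2], a0_fix))
    best <- NULL
    for (c0s in c(0, min(g))) {
      o <- tryCatch(optim(c(c0s, max(gmax - c0s, 1e-8 * gmax)), obj2,
                          method = "L-BFGS-B", lower = c(0, 0)),
                    error = function(e) NULL)
      if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
    }
    if (is.null(best)) {
      warning("linear variogram fit failed; pure nugget fallback")
      return(variogram_model(family, mean(g), 0, a0_fix, day,
                             diagnostics = list(wsse = obj(c(mean(g), 0, a0_fix)),
                                                fallback = TRUE)))
    }
    return(variogram_model(family, best$par[1], best$par[2], a0_fix, day,
                           diagnostics = list(wsse = best$value)))
  }
  a0_starts <- emp$max_lag * c(0.1, 0.25, 0.5, 1.0)
  best <- NULL
  for (a0s in a0_starts) {
    for (c0s in c(0, min(g))) {
      start <- c(c0s, max(gmax - c0s, 1e-8 * gmax), a0s)
      o <- tryCatch(
        optim(start, obj, method = "L-BFGS-B",
              lower = c(0, 0, 1e-6 * emp$max_lag),
              upper = c(2 * gmax, 3 * gmax, emp$max_lag),
              control = list(parscale = c(gmax, gmax, emp$max_lag),
                             maxit = 500)),
        error = function(e) NULL)
      if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
    }
  }
  if (is.null(best)) {
    warning("variogram optimization failed on all starts; pure nugget fallback")
    return(variogram_model(family, mean(g), 0, emp$max_lag, day,
                           diagnostics = list(fallback = TRUE)))
  }
  if (parsimony) {
    w <- if (weights == "np") np else np / pmax(g, 1e-10 * gmax)^2
    c0_nugget <- sum(w * g) / sum(w)
    sse0 <- sum(w * (g - c0_nugget)^2)
    m <- length(d)
    p_extra <- 2
    if (m - 3 >= 1 && best$value > .Machine$double.eps * sse0) {
      Fstat <- ((sse0 - best$value) / p_extra) / (best$value / (m - 3))
      if (Fstat < stats::qf(0.95, p_extra, m - 3)) {
        return(variogram_model(family, c0_nugget, 0, emp$max_lag, day,
                               diagnostics = list(wsse = sse0,
                                                  structured_wsse = best$value,
                                                  parsimony = TRUE)))
      }
    }
  }
  variogram_model(family, best$par[1], best$par[2], best$par[3], day,
                  diagnostics = list(wsse = best$value))
}

#' Fit a variogram to residuals by Gaussian maximum likelihood
#'
#' Fits (c0, c, a0) of a bounded variogram family directly to one day's
#' residual vector by maximising the Gaussian log-likelihood of the implied
#' covariance C(d) = c0 1(d=0) + c g(d; a0), profiling out an unknown
#' constant mean by generalized least squares. ML uses every pair's exact
#' separation rather than binned averages, which makes the range parameter
#' considerably better determined than a weighted-least-squares fit of the
#' binned empirical variogram; the WLS fit (from [fit_variogram()]) seeds the
#' optimizer. A likelihood-ratio guard against the pure-nugget model (level
#' 0.95) protects against spurious structure on spatially independent
#' residuals.
#'
#' Not available for the linear family (no valid stationary covariance);
#' those fall back to WLS.
#'
#' @param residuals numeric residual vector (NAs dropped with locations).
#' @param locations planar coordinates (columns x, y, metres).
#' @param family bounded variogram family.
#' @param emp optional precomputed empirical variogram (for the WLS seed).
#' @param parsimony apply the likelihood-ratio nugget guard.
#' @param day day index stored on the result.
#' @param ... passed to [empirical_variogram()] when `emp` is NULL.
#' @return a `pm_variogram` with `diagnostics$loglik` and
#'   `diagnostics$method = "ml"`.
#' @export
fit_variogram_ml <- function(residuals, locations, family = "exponential",
                             emp = NULL, parsimony = TRUE,
                             day = NA_integer_, ...) {
  family <- match.arg(family, VGM_FAMILIES)
  if (family == "linear") {
    if (is.null(emp)) emp <- empirical_variogram(residuals, locations, ...)
    return(fit_variogram(emp, family, day = day, parsimony = parsimony))
  }
  locations <- as.matrix(as.data.frame(locations)[, c("x", "y")])
  keep <- !is.na(residuals)
  z <- residuals[keep]
  loc <- locations[keep, , drop = FALSE]
  n <- length(z)
  if (n < 10) stop("need at least 10 non-missing residuals for ML fitting")
  D <- as.matrix(dist(loc))
  maxd <- max(D)
  s2 <- var(z)
  if (s2 == 0) {
    warning("constant residuals; returning zero variogram")
    return(variogram_model(family, 0, 0, maxd, day,
                           diagnostics = list(method = "ml", degenerate = TRUE)))
  }
  corr_fn <- function(h) switch(family,
    exponential = exp(-h),
    gaussian    = exp(-h^2),
    spherical   = ifelse(h < 1, 1 - 1.5 * h + 0.5 * h^3, 0),
    circular    = {
      hh <- pmin(h, 1)
      ifelse(h < 1, (2 / pi) * (acos(hh) - hh * sqrt(pmax(0, 1 - hh^2))), 0)
    })
  negll <- function(par) {
    c0 <- exp(par[1]); cc <- exp(par[2]); a0 <- exp(par[3])
    if (!is.finite(c0 + cc + a0) || a0 > 100 * maxd) return(1e10)
    C <- cc * corr_fn(D / a0)
    diag(C) <- c0 + cc + 1e-12 * s2
    ch <- tryCatch(chol(C), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    # profile a constant mean by GLS
    v1 <- backsolve(ch, rep(1, n), transpose = TRUE)
    vz <- backsolve(ch, z, transpose = TRUE)
    mu <- sum(v1 * vz) / sum(v1^2)
    r <- vz - mu * v1
    sum(log(diag(ch))) + 0.5 * sum(r^2) + 0.5 * n * log(2 * pi)
  }
  if (is.null(emp)) {
    emp <- tryCatch(empirical_variogram(z, loc, ...), error = function(e) NULL)
  }
  seed_fit <- if (!is.null(emp)) {
    tryCatch(suppressWarnings(fit_variogram(emp, family, parsimony = FALSE)),
             error = function(e) NULL)
  }
  starts <- list(c(0.1 * s2, 0.9 * s2, maxd / 6),
                 c(0.5 * s2, 0.5 * s2, maxd / 3))
  if (!is.null(seed_fit) && seed_fit$c > 0) {
    starts <- c(list(c(max(seed_fit$c0, 1e-4 * s2), seed_fit$c, seed_fit$a0)),
                starts)
  }
  best <- NULL
  for (st in starts) {
    o <- tryCatch(optim(log(pmax(st, 1e-12)), negll, method = "Nelder-Mead",
                        control = list(maxit = 500, reltol = 1e-10)),
                  error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best) || best$value >= 1e10) {
    warning("ML variogram fit failed; pure nugget fallback")
    return(variogram_model(family, s2, 0, maxd, day,
                           diagnostics = list(method = "ml", fallback = TRUE)))
  }
  par <- exp(best$par)
  if (parsimony) {
    # nugget-only model: iid N(mu, c0), analytic ML
    sig2 <- mean((z - mean(z))^2)
    ll0 <- -0.5 * n * (log(2 * pi * sig2) + 1)
    lrt <- 2 * ((-best$value) - ll0)
    if (lrt < stats::qchisq(0.95, 2)) {
      return(variogram_model(family, sig2, 0, maxd, day,
                             diagnostics = list(method = "ml", loglik = ll0,
                                                parsimony = TRUE)))
    }
  }
  variogram_model(family, par[1], par[2], min(par[3], 100 * maxd), day,
                  diagnostics = list(method = "ml", loglik = -best$value))
}

# day-level fitting dispatcher: ML for bounded families, WLS for linear or
# when explicitly requested
fit_day_variogram <- function(residuals, locations, family = "exponential",
                              emp = NULL, method = c("ml", "wls"),
                              day = NA_integer_, ...) {
  method <- match.arg(method)
  if (method == "ml" && family != "linear") {
    fit_variogram_ml(residuals, locations, family, emp = emp, day = day, ...)
  } else {
    if (is.null(emp)) emp <- empirical_variogram(residuals, locations, ...)
    fit_variogram(emp, family, day = day)
  }
}

#' Ordinary kriging of one day's residuals
#'
#' Solves the ordinary-kriging system in variogram form: the (n+1) x (n+1)
#' augmented matrix \[\[Gamma, 1\], \[1', 0\]\] against \[gamma(s_i, s0); 1\],
#' yielding weights that sum to 1 (unbiasedness) and a Lagrange multiplier.
#' The estimate is the weighted sum of residuals; the kriging variance is
#' lambda' gamma0 + mu. Stations sharing identical coordinates are averaged
#' before solving.
#'
#' @param residuals numeric residuals at stations (NAs dropped).
#' @param locations planar station coordinates (columns x, y, metres).
#' @param vgm a `pm_variogram`.
#' @param targets data.frame/matrix of target x, y.
#' @param return_weights also return the weight matrix (targets x stations).
#' @return data.frame (`estimate`, `variance`), optionally with attribute
#'   `"weights"`.
#' @export
krige <- function(residuals, locations, vgm, targets, return_weights = FALSE) {
  stopifnot(inherits(vgm, "pm_variogram"))
  locations <- as.matrix(as.data.frame(locations)[, c("x", "y")])
  keep <- !is.na(residuals)
  residuals <- residuals[keep]
  locations <- locations[keep, , drop = FALSE]
  # average duplicated coordinates (singular system otherwise)
  key <- paste(locations[, 1], locations[, 2])
  if (anyDuplicated(key)) {
    agg <- tapply(residuals, key, mean)
    first <- !duplicated(key)
    locations <- locations[first, , drop = FALSE]
    residuals <- as.numeric(agg[paste(locations[, 1], locations[, 2])])
  }
  n <- length(residuals)
  if (n < 2) stop("need at least 2 stations to krige")
  targets <- as.matrix(as.data.frame(targets)[, c("x", "y")])
  D <- as.matrix(dist(locations))
  A <- rbind(cbind(variogram_value(D, vgm$family, vgm$c0, vgm$c, vgm$a0), 1),
             c(rep(1, n), 0))
  d0 <- sqrt(outer(targets[, 1], locations[, 1], "-")^2 +
             outer(targets[, 2], locations[, 2], "-")^2)
  G0 <- variogram_value(d0, vgm$family, vgm$c0, vgm$c, vgm$a0)
  B <- rbind(t(G0), 1)
  sol <- tryCatch(solve(A, B), error = function(e) {
    stop("singular kriging system: ", conditionMessage(e))
  })
  W <- t(sol[seq_len(n), , drop = FALSE])        # targets x stations
  mu_lag <- sol[n + 1, ]
  est <- as.numeric(W %*% residuals)
  kvar <- pmax(0, rowSums(W * G0) + mu_lag)
  out <- data.frame(estimate = est, variance = kvar)
  if (return_weights) attr(out, "weights") <- W
  out
}

#' Leave-one-station-out kriging cross-validation
#'
#' Each station's residual is predicted by ordinary kriging from all the
#' others under the supplied variogram; returns the predictions and RMSE.
#'
#' @inheritParams krige
#' @return list with `predicted`, `observed`, `rmse`.
#' @export
loocv_krige <- function(residuals, locations, vgm) {
  locations <- as.data.frame(locations)[, c("x", "y")]
  keep <- !is.na(residuals)
  res <- residuals[keep]
  loc <- locations[keep, , drop = FALSE]
  n <- length(res)
  pred <- vapply(seq_len(n), function(i) {
    krige(res[-i], loc[-i, , drop = FALSE], vgm,
          loc[i, , drop = FALSE])$estimate
  }, numeric(1))
  list(predicted = pred, observed = res,
       rmse = sqrt(mean((pred - res)^2)))
}

#' Select a variogram family by leave-one-station-out cross-validation
#'
#' Each candidate family is fitted to the day's residuals, then scored by
#' leave-one-station-out kriging RMSE. The family with the lowest RMSE wins,
#' with ties broken towards the exponential family; because LOOCV scores of
#' competing families typically differ by far less than their sampling noise,
#' a tie is declared unless the competitor's improvement over the exponential
#' family is significant by a one-sided paired t-test (level 0.05) on the
#' station-wise squared errors. Candidates
#' whose fit or scoring fails are skipped; if all fail, a pure-nugget
#' exponential model is returned with a warning.
#'
#' @param residuals day residuals at stations.
#' @param locations planar station coordinates.
#' @param families candidate family names.
#' @param emp optional precomputed `pm_empirical_variogram`.
#' @param method parameter fitting method per family: `"ml"` (default; linear
#'   falls back to WLS) or `"wls"`.
#' @param ... passed to [empirical_variogram()] when `emp` is NULL.
#' @return the selected `pm_variogram`, with `diagnostics$loocv_rmse` and a
#'   `diagnostics$scores` table over the candidates.
#' @export
select_family_loocv <- function(residuals, locations, families = VGM_FAMILIES,
                                emp = NULL, method = "ml", ...) {
  families <- match.arg(families, VGM_FAMILIES, several.ok = TRUE)
  if (is.null(emp)) emp <- empirical_variogram(residuals, locations, ...)
  fits <- list()
  errs <- list()
  scores <- rep(NA_real_, length(families))
  names(scores) <- families
  for (f in families) {
    fit <- tryCatch(
      suppressWarnings(fit_day_variogram(residuals, locations, f, emp = emp,
                                         method = method)),
      error = function(e) NULL)
    if (is.null(fit)) next
    cv <- tryCatch(loocv_krige(residuals, locations, fit),
                   error = function(e) NULL)
    if (is.null(cv)) next
    fits[[f]] <- fit
    errs[[f]] <- cv$predicted - cv$observed
    scores[f] <- cv$rmse
  }
  if (all(is.na(scores))) {
    warning("all candidate families failed; pure-nugget exponential fallback")
    g <- var(residuals, na.rm = TRUE)
    return(variogram_model("exponential", if (is.finite(g)) g else 0, 0,
                           emp$max_lag,
                           diagnostics = list(fallback = TRUE)))
  }
  pick <- names(scores)[which.min(scores)]
  if ("exponential" %in% names(fits) && pick != "exponential") {
    d <- errs[["exponential"]]^2 - errs[[pick]]^2
    se <- sd(d) / sqrt(length(d))
    tcrit <- stats::qt(0.95, length(d) - 1)
    if (se == 0 || mean(d) <= tcrit * se) pick <- "exponential"
  }
  out <- fits[[pick]]
  out$diagnostics$loocv_rmse <- scores[[pick]]
  out$diagnostics$scores <- scores
  out
}

#' Fit daily variograms and krige residual surfaces for a year
#'
#' For each day with at least `min_stations` non-missing residuals, estimates
#' the empirical variogram, fits (or selects) a variogram model, and kriges
#' the residuals to the grid. Days below the station threshold are flagged
#' `no kriging` and contribute an all-zero surface (residual term 0). The
#' per-day parameter table (family, nugget, partial sill, a0, effective
#' range) tracks the seasonal evolution of residual autocorrelation.
#'
#' @param resid_matrix stations x days matrix of log-scale residuals.
#' @param locations station planar coordinates (columns x, y).
#' @param grid list(xmin, xmax, ymin, ymax, cell) in metres, or a data.frame
#'   of target x, y.
#' @param family a fixed family, or `"select"` for per-day LOOCV selection.
#' @param min_stations minimum stations required to krige a day.
#' @param method per-day parameter fitting: `"ml"` or `"wls"`.
#' @param n_bins,max_lag,min_pairs empirical-variogram settings.
#' @return list: `params` data.frame (day, family, kriged, nugget,
#'   partial_sill, a0, effective_range, loocv_rmse), `surfaces` (grid-points x
#'   days matrix), `grid` (the target coordinates).
#' @export
daily_surfaces <- function(resid_matrix, locations, grid,
                           family = "exponential", min_stations = 10,
                           method = "ml",
                           n_bins = 12, max_lag = NULL, min_pairs = 5) {
  resid_matrix <- as.matrix(resid_matrix)
  n_days <- ncol(resid_matrix)
  targets <- if (is.data.frame(grid)) grid else grid_points(grid)
  surf <- matrix(0, nrow(targets), n_days)
  params <- data.frame(day = seq_len(n_days), family = NA_character_,
                       kriged = FALSE, nugget = NA_real_,
                       partial_sill = NA_real_, a0 = NA_real_,
                       effective_range = NA_real_, loocv_rmse = NA_real_,
                       stringsAsFactors = FALSE)
  for (t in seq_len(n_days)) {
    res <- resid_matrix[, t]
    ok <- !is.na(res)
    if (sum(ok) < min_stations) next  # flagged: no kriging, zero surface
    vgm <- tryCatch(suppressWarnings({
      emp <- empirical_variogram(res, locations, n_bins, max_lag, min_pairs)
      if (identical(family, "select")) {
        select_family_loocv(res, locations, emp = emp, method = method)
      } else {
        fit_day_variogram(res, locations, family, emp = emp, method = method,
                          day = t)
      }
    }), error = function(e) NULL)
    if (is.null(vgm)) next
    params$family[t] <- vgm$family
    params$kriged[t] <- TRUE
    params$nugget[t] <- vgm$c0
    params$partial_sill[t] <- vgm$c
    params$a0[t] <- if (vgm$c > 0) vgm$a0 else NA_real_
    params$effective_range[t] <- if (vgm$c > 0) vgm$effective_range else NA_real_
    if (!is.null(vgm$diagnostics$loocv_rmse)) {
      params$loocv_rmse[t] <- vgm$diagnostics$loocv_rmse
    }
    if (vgm$c0 == 0 && vgm$c == 0) next  # degenerate: zero surface
    surf[, t] <- krige(res, locations, vgm, targets)$estimate
  }
  list(params = params, surfaces = surf, grid = targets)
}

#' Expand a grid specification into cell-centre points
#' @param grid list(xmin, xmax, ymin, ymax, cell), metres.
#' @return data.frame of x, y cell centres.
#' @export
grid_points <- function(grid) {
  stopifnot(all(c("xmin", "xmax", "ymin", "ymax", "cell") %in% names(grid)))
  if (grid$xmax <= grid$xmin || grid$ymax <= grid$ymin || grid$cell <= 0) {
    stop("degenerate grid specification")
  }
  xs <- seq(grid$xmin + grid$cell / 2, grid$xmax, by = grid$cell)
  ys <- seq(grid$ymin + grid$cell / 2, grid$ymax, by = grid$cell)
  expand.grid(x = xs, y = ys, KEEP.OUT.ATTRS = FALSE)
}

#' Area-average of point estimates over a region polygon
#'
#' The block estimate is the discretized average of point values whose
#' locations fall inside the polygon (even-odd rule). Refining the
#' discretization converges to the areal mean for smooth surfaces.
#'
#' @param points data.frame with columns x, y, value.
#' @param polygon two-column matrix of polygon vertices (closed implicitly).
#' @return scalar block mean.
#' @export
block_mean <- function(points, polygon) {
  stopifnot(all(c("x", "y", "value") %in% names(points)))
  polygon <- as.matrix(polygon)
  inside <- point_in_polygon(points$x, points$y, polygon)
  if (!any(inside)) stop("polygon does not intersect any point locations")
  mean(points$value[inside])
}

# even-odd ray casting; vertices need not repeat the first point
point_in_polygon <- function(px, py, polygon) {
  nv <- nrow(polygon)
  xs <- polygon[, 1]; ys <- polygon[, 2]
  inside <- rep(FALSE, length(px))
  j <- nv
  for (i in seq_len(nv)) {
    crosses <- ((ys[i] > py) != (ys[j] > py)) &
      (px < (xs[j] - xs[i]) * (py - ys[i]) / (ys[j] - ys[i]) + xs[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Look up a day-of-year residual surface for another year
#'
#' Transfers a fitted year's daily residual surfaces to a different year by
#' day-of-year, under the assumption that residual variograms change little
#' between years; the result is marked as an extrapolation.
#'
#' @param surfaces result of [daily_surfaces()].
#' @param day_of_year 1-based day-of-year to look up.
#' @return data.frame (x, y, value) with attribute `"extrapolated" = TRUE`.
#' @export
residual_surface_lookup <- function(surfaces, day_of_year) {
  stopifnot(day_of_year >= 1, day_of_year <= ncol(surfaces$surfaces))
  out <- data.frame(surfaces$grid, value = surfaces$surfaces[, day_of_year])
  attr(out, "extrapolated") <- TRUE
  out
}
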