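# Non-linear additive modelling of log PM2.5 and bootstrap-aggregated
# ensembles: members are penalized additive fits on bootstrap resamples, each
# scored by its out-of-bag R2; the ensemble prediction is the R2^2-weighted
# mean with a weighted standard deviation as the uncertainty measure.

#' Fit a penalized additive model on log concentrations
#'
#' The mean model is a sum of univariate smooths of the temporal basis
#' functions and each covariate, optionally a bivariate smooth of the wind
#' vector components. Each smooth's basis dimension is capped (default 10) to
#' limit effective degrees of freedom and prevent overfitting. Fitting is
#' delegated to mgcv (`bam` for large tables, `gam` otherwise), with a
#' Gaussian response on the log scale.
#'
#' @param data modelling table (one row per station-day).
#' @param response response column name (default `"log_pm25"`).
#' @param smooth_terms character vector of columns entering as univariate
#'   smooths.
#' @param wind_pair optional length-2 character vector naming the eastward and
#'   northward wind components, entering as one bivariate smooth.
#' @param linear_terms optional columns entering linearly.
#' @param max_df maximum degrees of freedom per smooth term.
#' @param select add mgcv's double-penalty shrinkage so that uninformative
#'   smooths can be penalized to zero (used during stepwise selection).
#' @return object of class `pm_additive_fit`: the mgcv `model`, the term
#'   specification, `r2_train` (1 - SSE/SST) and fitted values.
#' @export
fit_additive <- function(data, response = "log_pm25", smooth_terms = character(0),
                         wind_pair = NULL, linear_terms = character(0),
                         max_df = 10, select = FALSE) {
  all_terms <- c(response, smooth_terms, wind_pair, linear_terms)
  missing_cols <- setdiff(all_terms, names(data))
  if (length(missing_cols) > 0) {
    stop("columns not in data: ", paste(missing_cols, collapse = ", "))
  }
  if (length(smooth_terms) == 0 && is.null(wind_pair) &&
      length(linear_terms) == 0) {
    stop("no model terms supplied")
  }
  y <- data[[response]]
  if (anyNA(y)) stop("missing values in response")
  parts <- character(0)
  for (v in smooth_terms) {
    k <- min(max_df, length(unique(data[[v]])))
    parts <- c(parts,
               if (k >= 3) sprintf("s(%s, k = %d)", v, k) else v)
  }
  if (!is.null(wind_pair)) {
    stopifnot(length(wind_pair) == 2)
    parts <- c(parts, sprintf("s(%s, %s, k = %d)", wind_pair[1], wind_pair[2],
                              max(2 * max_df, 10)))
  }
  parts <- c(parts, linear_terms)
  fml <- stats::as.formula(paste(response, "~", paste(parts, collapse = " + ")))
  n <- nrow(data)
  model <- if (sd(y) == 0) {
    # degenerate constant response: intercept-only fit
    lm(stats::as.formula(paste(response, "~ 1")), data = data)
  } else if (n >= 8000) {
    mgcv::bam(fml, data = data, method = "fREML", discrete = TRUE,
              select = select)
  } else {
    mgcv::gam(fml, data = data, method = "REML", select = select)
  }
  fit_vals <- as.numeric(fitted(model))
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sum((y - fit_vals)^2) / sst else 0
  ranges <- lapply(data[, c(smooth_terms, wind_pair, linear_terms), drop = FALSE],
                   range)
  structure(
    list(model = model, response = response, smooth_terms = smooth_terms,
         wind_pair = wind_pair, linear_terms = linear_terms, max_df = max_df,
         r2_train = r2, n = n, train_ranges = ranges),
    class = "pm_additive_fit"
  )
}

#' Predict from a single additive fit
#'
#' @param object a `pm_additive_fit`.
#' @param newdata rows carrying every covariate the terms need; an error names
#'   any missing column. Rows with a covariate outside the training range are
#'   flagged in the `"extrapolated"` attribute.
#' @param ... unused.
#' @return numeric vector of log-scale predictions.
#' @export
predict.pm_additive_fit <- function(object, newdata, ...) {
  need <- c(object$smooth_terms, object$wind_pair, object$linear_terms)
  missing_cols <- setdiff(need, names(newdata))
  if (length(missing_cols) > 0) {
    stop("missing covariate column(s): ", paste(missing_cols, collapse = ", "))
  }
  extrap <- rep(FALSE, nrow(newdata))
  for (v in need) {
    rg <- object$train_ranges[[v]]
    extrap <- extrap | newdata[[v]] < rg[1] | newdata[[v]] > rg[2]
  }
  out <- as.numeric(predict(object$model, newdata = newdata))
  attr(out, "extrapolated") <- extrap
  out
}

#' Per-term explained-variance decomposition
#'
#' Refits the model dropping one term at a time; a term's contribution is the
#' drop in training R2 when it is removed (multivariate decomposition), and
#' its univariate R2 from a single-term fit is reported alongside.
#'
#' @param data modelling table.
#' @param response response column.
#' @param smooth_terms terms to decompose.
#' @param max_df smooth basis cap.
#' @return data.frame (term, univariate_r2, multivariate_drop).
#' @export
variance_decomposition <- function(data, response = "log_pm25", smooth_terms,
                                   max_df = 10) {
  full <- fit_additive(data, response, smooth_terms, max_df = max_df)
  rows <- lapply(seq_along(smooth_terms), function(i) {
    uni <- fit_additive(data, response, smooth_terms[i], max_df = max_df)
    red_terms <- smooth_terms[-i]
    red_r2 <- if (length(red_terms) > 0) {
      fit_additive(data, response, red_terms, max_df = max_df)$r2_train
    } else 0
    data.frame(term = smooth_terms[i], univariate_r2 = uni$r2_train,
               multivariate_drop = full$r2_train - red_r2,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "full_r2") <- full$r2_train
  out
}

#' Ensemble weights from member R2 values
#'
#' Weights are proportional to the square of each member's R2:
#' w_i = (R2_i)^2 / sum_j (R2_j)^2, so better members dominate superlinearly.
#' If every R2 is zero a uniform weighting is returned with a warning.
#'
#' @param r2 numeric vector of member R2 values in \[0, 1\] (negative values
#'   are clamped to 0: a member no better than the mean gets zero weight).
#' @return weights summing to 1.
#' @export
ensemble_weights <- function(r2) {
  stopifnot(length(r2) >= 1, all(is.finite(r2)))
  if (any(r2 > 1)) stop("R2 above 1 supplied")
  r2 <- pmax(r2, 0)
  s <- sum(r2^2)
  if (s == 0) {
    warning("all member R2 are 0; using uniform weights")
    return(rep(1 / length(r2), length(r2)))
  }
  r2^2 / s
}

#' Fit a bagged ensemble of additive models
#'
#' Draws `B` bootstrap resamples of the rows (with replacement, same size n),
#' fits the additive model on each, and scores each member by R2 on its
#' out-of-bag rows (the ~36.8% of rows absent from its resample). Weights
#' follow [ensemble_weights()]. A resample producing a degenerate design is
#' redrawn (up to 10 times).
#'
#' @param data modelling table.
#' @param B number of bootstrap members (1000 in production; tests use 25-50).
#' @param seed RNG seed; fixing it makes the ensemble bit-reproducible.
#' @param oob_r2_scale scale on which member OOB R2 is computed: `"log"`
#'   (model scale, default) or `"concentration"`.
#' @inheritParams fit_additive
#' @return object of class `pm_ensemble`: `members` (list of
#'   `pm_additive_fit`), `oob_r2`, `weights`, in-bag index lists, `seed`.
#' @export
bagging_fit <- function(data, response = "log_pm25", smooth_terms,
                        wind_pair = NULL, linear_terms = character(0),
                        max_df = 10, B = 1000, seed = 1,
                        oob_r2_scale = c("log", "concentration")) {
  stopifnot(B >= 1)
  oob_r2_scale <- match.arg(oob_r2_scale)
  n <- nrow(data)
  set.seed(seed)
  members <- vector("list", B)
  inbag <- vector("list", B)
  oob_r2 <- numeric(B)
  y <- data[[response]]
  for (b in seq_len(B)) {
    fit <- NULL
    for (try in seq_len(10)) {
      idx <- sample.int(n, n, replace = TRUE)
      fit <- tryCatch(
        fit_additive(data[idx, , drop = FALSE], response, smooth_terms,
                     wind_pair, linear_terms, max_df),
        error = function(e) NULL)
      if (!is.null(fit)) break
    }
    if (is.null(fit)) stop("degenerate bootstrap design after 10 redraws (member ", b, ")")
    oob <- setdiff(seq_len(n), unique(idx))
    mu <- predict(fit, data[oob, , drop = FALSE])
    if (oob_r2_scale == "concentration") {
      obs <- exp(y[oob]); pred <- exp(mu)
    } else {
      obs <- y[oob]; pred <- mu
    }
    sst <- sum((obs - mean(obs))^2)
    oob_r2[b] <- if (sst > 0) 1 - sum((obs - pred)^2) / sst else 0
    members[[b]] <- fit
    inbag[[b]] <- idx
  }
  structure(
    list(members = members, inbag = inbag, oob_r2 = oob_r2,
         weights = ensemble_weights(oob_r2), B = B, seed = seed, n = n,
         response = response),
    class = "pm_ensemble"
  )
}

#' @export
print.pm_ensemble <- function(x, ...) {
  cat(sprintf("<pm_ensemble> B = %d members on n = %d rows; OOB R2 %.3f (median), weights in [%.4f, %.4f]\n",
              x$B, x$n, median(x$oob_r2), min(x$weights), max(x$weights)))
  invisible(x)
}

#' Weighted ensemble mean and standard deviation
#'
#' Aggregates member predictions mu_i with weights w_i into the final estimate
#' mu_f = sum_i w_i mu_i and the uncertainty
#' sigma_f = sqrt( sum_i w_i (mu_i - mu_f)^2 / ( ((M-1)/M) sum_i w_i ) ),
#' where M is the number of nonzero weights (sigma_f = 0 when M = 1). With
#' equal weights sigma_f reduces to the ordinary sample SD of the members.
#'
#' @param pred_matrix rows = prediction points, columns = members (log scale).
#' @param weights member weights (summing to 1).
#' @return data.frame with `mean_log`, `sd_log`, and `M`.
#' @export
weighted_ensemble_stats <- function(pred_matrix, weights) {
  pred_matrix <- as.matrix(pred_matrix)
  stopifnot(ncol(pred_matrix) == length(weights), all(weights >= 0))
  sw <- sum(weights)
  stopifnot(sw > 0)
  M <- sum(weights > 0)
  mu <- as.numeric(pred_matrix %*% weights) / sw
  if (M <= 1) {
    sdv <- rep(0, nrow(pred_matrix))
  } else {
    dev2 <- sweep(pred_matrix, 1, mu)^2
    sdv <- sqrt(as.numeric(dev2 %*% weights) / (((M - 1) / M) * sw))
  }
  data.frame(mean_log = mu, sd_log = sdv, M = M)
}

#' Predict from a bagged ensemble
#'
#' Every member predicts `newdata` on the log scale; predictions are combined
#' with [weighted_ensemble_stats()]. An optional 95% interval is
#' mean_log +/- 1.96 sd_log.
#'
#' @param object a `pm_ensemble`.
#' @param newdata rows carrying all covariates the members need.
#' @param interval add `lwr_log`/`upr_log` 95% bounds.
#' @param ... unused.
#' @return data.frame with `mean_log`, `sd_log`, `M`, `extrapolated`.
#' @export
predict.pm_ensemble <- function(object, newdata, interval = FALSE, ...) {
  P <- matrix(NA_real_, nrow(newdata), object$B)
  extrap <- rep(FALSE, nrow(newdata))
  for (b in seq_len(object$B)) {
    p <- predict(object$members[[b]], newdata)
    P[, b] <- p
    extrap <- extrap | attr(p, "extrapolated")
  }
  out <- weighted_ensemble_stats(P, object$weights)
  out$extrapolated <- extrap
  if (interval) {
    out$lwr_log <- out$mean_log - 1.96 * out$sd_log
    out$upr_log <- out$mean_log + 1.96 * out$sd_log
  }
  out
}

#' Out-of-bag ensemble predictions on the training table
#'
#' For each training row, only members for which the row was out-of-bag
#' contribute, with weights renormalized over those members; a member never
#' predicts its own in-bag rows. Rows that are in-bag for every member (rare
#' for moderate B) get NA.
#'
#' @param ensemble a `pm_ensemble`.
#' @param data the training table the ensemble was fitted on.
#' @return data.frame (`mean_log`, `n_members`) with one row per data row.
#' @export
oob_ensemble_predictions <- function(ensemble, data) {
  n <- nrow(data)
  stopifnot(n == ensemble$n)
  num <- numeric(n)
  den <- numeric(n)
  cnt <- integer(n)
  for (b in seq_len(ensemble$B)) {
    oob <- setdiff(seq_len(n), unique(ensemble$inbag[[b]]))
    if (length(oob) == 0) next
    mu <- predict(ensemble$members[[b]], data[oob, , drop = FALSE])
    w <- ensemble$weights[b]
    num[oob] <- num[oob] + w * mu
    den[oob] <- den[oob] + w
    cnt[oob] <- cnt[oob] + 1L
  }
  mean_log <- ifelse(den > 0, num / den, NA_real_)
  data.frame(mean_log = mean_log, n_members = cnt)
}

#' Expected unique fraction of a bootstrap resample
#'
#' A size-n resample drawn with replacement contains on average
#' 1 - (1 - 1/n)^n of the distinct rows (-> 1 - 1/e ~ 63.2% as n grows); the
#' complement ~36.8% forms the out-of-bag validation set.
#'
#' @param n sample size.
#' @param simulate if > 0, also estimate the fraction empirically over this
#'   many resamples.
#' @param seed RNG seed for the simulation.
#' @return list with `expected` (closed form) and, when simulated, `empirical`.
#' @export
bootstrap_unique_fraction <- function(n, simulate = 0, seed = 1) {
  expected <- 1 - (1 - 1 / n)^n
  out <- list(expected = expected)
  if (simulate > 0) {
    set.seed(seed)
    fr <- vapply(seq_len(simulate), function(i) {
      length(unique(sample.int(n, n, replace = TRUE))) / n
    }, numeric(1))
    out$empirical <- mean(fr)
  }
  out
}
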