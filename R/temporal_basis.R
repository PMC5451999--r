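# Temporal basis functions: SVD completion of the station x day panel and
# extraction/smoothing of the first two right singular vectors, which serve as
# shared seasonal-trend predictors f1(t), f2(t).

#' Impute missing panel entries by iterative truncated SVD
#'
#' Missing entries are initialised at their day (column) means, then the matrix
#' is repeatedly factorised, truncated to `rank`, and the missing entries
#' refilled from the reconstruction until the relative change of the imputed
#' values falls below `tol`. Observed entries are never modified.
#'
#' @param panel a `pm_panel` with missing fraction below 50%.
#' @param rank reconstruction rank (default 2, matching the two temporal basis
#'   functions retained downstream).
#' @param tol relative-change convergence tolerance.
#' @param max_iter iteration cap; non-convergence returns the last iterate
#'   with a warning and `converged = FALSE` attribute.
#' @return the completed `pm_panel` (attribute `"svd_impute"` records
#'   iterations and convergence).
#' @export
svd_impute <- function(panel, rank = 2, tol = 1e-6, max_iter = 500) {
  stopifnot(inherits(panel, "pm_panel"))
  M <- panel$values
  miss <- is.na(M)
  if (!any(miss)) return(panel)
  if (mean(miss) >= 0.5) {
    stop(sprintf("missing fraction %.1f%% >= 50%%: too sparse for SVD imputation",
                 100 * mean(miss)))
  }
  if (rank > min(dim(M))) stop("rank exceeds matrix dimensions")
  if (any(rowSums(!miss) == 0)) {
    stop("station with all entries missing: ",
         rownames(M)[which(rowSums(!miss) == 0)[1]])
  }
  if (any(colSums(!miss) == 0)) {
    stop("day with all entries missing: ",
         colnames(M)[which(colSums(!miss) == 0)[1]])
  }
  col_means <- colMeans(M, na.rm = TRUE)
  X <- M
  for (j in seq_len(ncol(X))) X[miss[, j], j] <- col_means[j]
  converged <- FALSE
  iter <- 0
  for (iter in seq_len(max_iter)) {
    sv <- svd(X, nu = rank, nv = rank)
    recon <- sv$u %*% (sv$d[seq_len(rank)] * t(sv$v))
    new_imp <- recon[miss]
    delta <- sqrt(sum((new_imp - X[miss])^2)) /
      max(sqrt(sum(X[miss]^2)), .Machine$double.eps)
    X[miss] <- new_imp
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("SVD imputation did not converge in ", max_iter, " iterations")
  }
  panel$values <- X
  attr(panel, "svd_impute") <- list(rank = rank, iterations = iter,
                                    converged = converged)
  panel
}

#' Extract temporal basis functions from a completed log-scale panel
#'
#' Each station's series is centred on its own mean over days (removing
#' between-station level differences so the basis captures the temporal shape
#' shared across stations) and the centred station x day matrix is decomposed
#' by SVD; the first `n_basis` right singular vectors are the raw temporal
#' basis vectors b1(t), b2(t). Signs are fixed so that each vector is positive
#' in mid-winter (day-of-year 15), making "high in winter" the positive
#' direction.
#'
#' @param panel a complete `pm_panel`, normally log-scale.
#' @param n_basis number of basis functions (1 or 2).
#' @return object of class `pm_temporal_basis` with fields `days`, `b1`, `b2`,
#'   singular values `d`, and `variance_fraction` per component. `f1`/`f2` are
#'   NULL until [smooth_basis()] is applied.
#' @export
extract_basis <- function(panel, n_basis = 2) {
  stopifnot(inherits(panel, "pm_panel"), n_basis %in% c(1L, 2L))
  M <- panel$values
  if (anyNA(M)) stop("panel has missing entries; impute first")
  C <- sweep(M, 1, rowMeans(M))
  total <- sum(C^2)
  if (total < .Machine$double.eps * length(C)) {
    stop("degenerate panel: no temporal variation after centring")
  }
  sv <- svd(C, nu = 0, nv = n_basis)
  b <- sv$v
  winter_day <- which.min(abs(panel$days - 15L))
  for (k in seq_len(n_basis)) {
    s <- sign(b[winter_day, k])
    if (s == 0) s <- sign(sum(b[, k]))
    if (s < 0) b[, k] <- -b[, k]
  }
  structure(
    list(days = panel$days,
         b1 = b[, 1],
         b2 = if (n_basis >= 2) b[, 2] else NULL,
         d = sv$d[seq_len(n_basis)],
         variance_fraction = sv$d[seq_len(n_basis)]^2 / sum(sv$d^2),
         f1 = NULL, f2 = NULL, smoothing_df = NULL),
    class = "pm_temporal_basis"
  )
}

#' Smooth the raw basis vectors with cubic smoothing splines
#'
#' Fits a cubic smoothing spline to each raw basis vector over the day index
#' and evaluates it at every day, giving the smooth seasonal predictors
#' f1(t), f2(t) used by the additive models.
#'
#' @param basis a `pm_temporal_basis` from [extract_basis()].
#' @param smoothing_df equivalent degrees of freedom of the spline, in
#'   (2, number of days).
#' @return the basis object with `f1` (and `f2`) populated.
#' @export
smooth_basis <- function(basis, smoothing_df = 12) {
  stopifnot(inherits(basis, "pm_temporal_basis"))
  T_ <- length(basis$days)
  if (!(smoothing_df > 2 && smoothing_df < T_)) {
    stop("smoothing_df must lie in (2, ", T_, ")")
  }
  fit1 <- smooth.spline(basis$days, basis$b1, df = smoothing_df,
                        all.knots = TRUE)
  basis$f1 <- predict(fit1, basis$days)$y
  if (!is.null(basis$b2)) {
    fit2 <- smooth.spline(basis$days, basis$b2, df = smoothing_df,
                          all.knots = TRUE)
    basis$f2 <- predict(fit2, basis$days)$y
  }
  basis$smoothing_df <- smoothing_df
  basis
}

#' @export
print.pm_temporal_basis <- function(x, ...) {
  cat(sprintf("<pm_temporal_basis> %d days, %d component(s); variance fractions: %s%s\n",
              length(x$days), if (is.null(x$b2)) 1L else 2L,
              paste(sprintf("%.3f", x$variance_fraction), collapse = ", "),
              if (is.null(x$f1)) " (unsmoothed)" else ""))
  invisible(x)
}

#' Export a temporal basis as a data.frame / CSV
#' @param basis a `pm_temporal_basis`.
#' @param path optional CSV path; when given, the table is also written there.
#' @return data.frame with columns day, b1, b2, f1, f2.
#' @export
basis_table <- function(basis, path = NULL) {
  df <- data.frame(day = basis$days, b1 = basis$b1,
                   b2 = if (is.null(basis$b2)) NA_real_ else basis$b2,
                   f1 = if (is.null(basis$f1)) NA_real_ else basis$f1,
                   f2 = if (is.null(basis$f2)) NA_real_ else basis$f2)
  if (!is.null(path)) write.csv(df, path, row.names = FALSE, quote = FALSE)
  df
}
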