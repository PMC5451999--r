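# Multicollinearity screening (VIF) and backward-stepwise covariate selection
# by AIC, using the same additive-model fitter as the ensemble so that
# selection and fitting are consistent.

#' Variance inflation factors
#'
#' VIF_j = 1 / (1 - R2_j), where R2_j is the coefficient of determination from
#' regressing candidate column j on all the others. Perfect collinearity is
#' reported as `Inf`, not an error, so the caller can drop the column.
#'
#' @param design data.frame or matrix of candidate covariate columns (no
#'   missing values, at least two columns, more rows than columns).
#' @return named numeric vector of VIFs.
#' @export
compute_vif <- function(design) {
  X <- as.data.frame(design)
  if (ncol(X) < 2) stop("need at least two candidate columns")
  if (nrow(X) < ncol(X) + 1) stop("need more rows than columns")
  if (anyNA(X)) stop("design contains missing values")
  if (any(vapply(X, function(v) var(v) == 0, logical(1)))) {
    stop("constant column in design: ",
         names(X)[which(vapply(X, function(v) var(v) == 0, logical(1)))[1]])
  }
  vif <- vapply(seq_along(X), function(j) {
    fit <- lm(X[[j]] ~ ., data = X[, -j, drop = FALSE])
    r2 <- summary(fit)$r.squared
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(vif) <- names(X)
  vif
}

#' Screen candidates by VIF
#'
#' Iteratively drops the column with the largest VIF until all remaining VIFs
#' fall below the threshold (conventional default 10).
#'
#' @param design candidate columns as for [compute_vif()].
#' @param threshold VIF cut-off.
#' @return list with `kept` (column names), `dropped`, and the final `vif`.
#' @export
vif_screen <- function(design, threshold = 10) {
  X <- as.data.frame(design)
  dropped <- character(0)
  while (ncol(X) >= 2) {
    v <- compute_vif(X)
    if (max(v) < threshold) break
    worst <- names(v)[which.max(v)]
    dropped <- c(dropped, worst)
    X <- X[, setdiff(names(X), worst), drop = FALSE]
  }
  list(kept = names(X), dropped = dropped,
       vif = if (ncol(X) >= 2) compute_vif(X) else setNames(1, names(X)))
}

#' Backward-stepwise covariate selection by AIC
#'
#' Starting from the full candidate set, the single smooth term whose removal
#' yields the lowest AIC is dropped, and removal is accepted as long as the
#' dropped term was not improving AIC by more than `aic_tol`: by the usual
#' delta-AIC-below-2 equivalence convention, a variable that buys less than
#' `aic_tol` of AIC does not earn its place and parsimony wins (penalized
#' smooths shrink uninformative terms towards zero effective df, which makes
#' their AIC contribution hover around zero — a strict "must lower AIC" rule
#' would keep them on noise). The procedure stops when every remaining
#' variable improves AIC by more than `aic_tol`. Ties are broken by keeping
#' the variable listed earlier in the candidate order. AIC comes from the
#' same penalized additive fitter used by
#' the ensemble, fitted with double-penalty shrinkage so an uninformative
#' smooth can be penalized to zero rather than spending degrees of freedom on
#' noise wiggles, keeping selection consistent with fitting.
#'
#' @param data modelling table containing `response` and all candidates.
#' @param response name of the response column (log concentration).
#' @param candidates character vector of candidate covariate names.
#' @param max_df maximum degrees of freedom per smooth term.
#' @param aic_tol AIC improvement a variable must provide to be retained.
#' @param verbose print the trace as it is built.
#' @return object of class `pm_selection_report`: `final` (selected names),
#'   `trace` data.frame (step, removed, aic_before, aic_after) and the
#'   starting `aic`.
#' @export
backward_stepwise_aic <- function(data, response, candidates, max_df = 10,
                                  aic_tol = 2, verbose = FALSE) {
  if (length(candidates) == 0) stop("empty candidate set")
  missing_cols <- setdiff(c(response, candidates), names(data))
  if (length(missing_cols) > 0) {
    stop("columns not in data: ", paste(missing_cols, collapse = ", "))
  }
  current <- candidates
  fit_aic <- function(vars) {
    if (length(vars) == 0) {
      fit <- lm(data[[response]] ~ 1)
      return(AIC(fit))
    }
    fit <- fit_additive(data, response = response, smooth_terms = vars,
                        max_df = max_df, select = TRUE)
    a <- AIC(fit$model)
    if (!is.finite(a)) {
      stop("non-finite AIC for fit with terms: ", paste(vars, collapse = ", "))
    }
    a
  }
  aic_now <- fit_aic(current)
  aic_start <- aic_now
  trace <- data.frame(step = integer(0), removed = character(0),
                      aic_before = numeric(0), aic_after = numeric(0),
                      stringsAsFactors = FALSE)
  step <- 0
  repeat {
    if (length(current) == 0) break
    cand_aic <- vapply(seq_along(current),
                       function(i) fit_aic(current[-i]), numeric(1))
    best <- which.min(cand_aic)  # first (earliest-listed survivorship) on ties
    if (cand_aic[best] >= aic_now + aic_tol) break
    step <- step + 1
    if (verbose) {
      message(sprintf("step %d: drop %s (AIC %.3f -> %.3f)",
                      step, current[best], aic_now, cand_aic[best]))
    }
    trace <- rbind(trace, data.frame(step = step, removed = current[best],
                                     aic_before = aic_now,
                                     aic_after = cand_aic[best],
                                     stringsAsFactors = FALSE))
    aic_now <- cand_aic[best]
    current <- current[-best]
  }
  if (length(current) == 0) {
    warning("all candidates removed; empty final set")
  }
  structure(list(final = current, trace = trace, aic_start = aic_start,
                 aic_final = aic_now),
            class = "pm_selection_report")
}

#' @export
print.pm_selection_report <- function(x, ...) {
  cat(sprintf("<pm_selection_report> %d variable(s) retained (AIC %.2f -> %.2f)\n",
              length(x$final), x$aic_start, x$aic_final))
  if (nrow(x$trace) > 0) {
    cat("removed:", paste(x$trace$removed, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Correlation screen for candidate covariates
#'
#' Utility reporting each candidate's correlation with the response; no fixed
#' significance rule is imposed — callers decide the cut.
#'
#' @param data modelling table.
#' @param response response column name.
#' @param candidates candidate column names.
#' @return data.frame (variable, correlation, abs_correlation), sorted by
#'   absolute correlation, descending.
#' @export
correlation_screen <- function(data, response, candidates) {
  r <- vapply(candidates, function(v) {
    cor(data[[v]], data[[response]], use = "complete.obs")
  }, numeric(1))
  out <- data.frame(variable = candidates, correlation = r,
                    abs_correlation = abs(r), stringsAsFactors = FALSE)
  out[order(-out$abs_correlation), ]
}
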