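#' Select an arm's predictor set from a BMA fit
#'
#' Two selection rules: `highest_posterior_model` (default) takes the
#' inclusion vector of the top-ranked model; `median_probability_model`
#' takes every column with posterior inclusion probability above 0.5.
#' An empty median-probability set falls back to the intercept-only
#' model with a warning and an explicit flag.
#'
#' @param result a `bma_result` for the arm.
#' @param rule selection rule.
#' @return character vector of selected column names; attributes `rule`
#'   and `null_model` (TRUE when the selection is intercept-only).
#' @export
select_predictors <- function(result,
                              rule = c("highest_posterior_model",
                                       "median_probability_model")) {
  stopifnot(inherits(result, "bma_result"))
  rule <- match.arg(rule)
  sel <- if (rule == "highest_posterior_model") {
    result$columns[result$gamma[1L, ]]
  } else {
    result$columns[result$pip > 0.5]
  }
  if (!length(sel) && rule == "median_probability_model")
    warning("median-probability model is empty; falling back to intercept only")
  structure(sel, rule = rule, null_model = length(sel) == 0L)
}

# OLS fit on the original scale; rank-deficient designs get the
# minimum-norm solution and fold-constant columns are dropped
ols_fit <- function(x, y, warn_context = NULL) {
  xd <- cbind(`(Intercept)` = 1, x)
  const <- c(FALSE, apply(x, 2L, function(col) length(unique(col)) == 1L))
  if (any(const)) {
    if (!is.null(warn_context))
      warning(sprintf("predictor column(s) constant in %s: %s (dropped for this fit)",
                      warn_context,
                      paste(colnames(xd)[const], collapse = ", ")))
    xd <- xd[, !const, drop = FALSE]
  }
  qx <- qr(xd)
  coef <- stats::setNames(rep(0, ncol(cbind(1, x))),
                          c("(Intercept)", colnames(x)))
  if (qx$rank < ncol(xd)) {
    if (!is.null(warn_context))
      warning(sprintf("singular design in %s; using minimum-norm solution", warn_context))
    sv <- svd(xd)
    pos <- sv$d > max(sv$d) * 1e-10
    b <- sv$v[, pos, drop = FALSE] %*%
      ((crossprod(sv$u[, pos, drop = FALSE], y)) / sv$d[pos])
    coef[colnames(xd)] <- drop(b)
  } else {
    coef[colnames(xd)] <- qr.coef(qx, y)
  }
  coef
}

ols_predict <- function(coef, xrow) {
  drop(coef[1L] + sum(coef[-1L] * xrow[names(coef)[-1L]]))
}

#' Leave-one-out factual and counterfactual outcome predictions
#'
#' For each patient in the received arm, the factual prediction is an
#' ordinary-least-squares fit (intercept + the arm's selected
#' predictors) on the received arm *excluding that patient*, evaluated
#' at the patient's covariates; the counterfactual prediction is an OLS
#' fit of the other arm's selected predictors on the entire other arm
#' (which never contains the patient), evaluated at the same
#' covariates. Predictor sets are fixed in advance (selected once on the
#' full per-arm samples) and predictions are raw linear predictors, not
#' clipped to the 0-27 scale.
#'
#' @param arm_data `coded_matrix` of the received arm (with outcomes).
#' @param other_arm_data `coded_matrix` of the other arm.
#' @param predictors_received,predictors_other selected column names per
#'   arm (from [select_predictors()]).
#' @return data frame with one row per patient of the received arm:
#'   factual/counterfactual predictions, optimal arm, PAI
#'   (= |factual - counterfactual|), `received_optimal` flag (a tie
#'   counts as optimal) and the observed outcome.
#' @export
loo_predictions <- function(arm_data, other_arm_data,
                            predictors_received, predictors_other) {
  stopifnot(inherits(arm_data, "coded_matrix"),
            inherits(other_arm_data, "coded_matrix"))
  received_arm <- unique(arm_data$arm)
  other_arm <- unique(other_arm_data$arm)
  stopifnot(length(received_arm) == 1L, length(other_arm) == 1L,
            received_arm != other_arm)
  xr <- arm_data$x[, predictors_received, drop = FALSE]
  yr <- arm_data$outcome
  xo <- other_arm_data$x[, predictors_other, drop = FALSE]
  yo <- other_arm_data$outcome
  n <- nrow(xr)
  if (n - 1L <= length(predictors_received) + 1L)
    stop("too few patients in the received arm for leave-one-out fits", call. = FALSE)
  if (nrow(xo) <= length(predictors_other) + 1L)
    stop("too few patients in the other arm", call. = FALSE)

  coef_other <- ols_fit(xo, yo, warn_context = sprintf("arm %s model", other_arm))
  xi_other <- arm_data$x[, predictors_other, drop = FALSE]

  factual <- counterfactual <- numeric(n)
  for (i in seq_len(n)) {
    coef_i <- ols_fit(xr[-i, , drop = FALSE], yr[-i],
                      warn_context = sprintf("fold %d of arm %s", i, received_arm))
    factual[i] <- ols_predict(coef_i, stats::setNames(xr[i, ], colnames(xr)))
    counterfactual[i] <- ols_predict(coef_other,
                                     stats::setNames(xi_other[i, ], colnames(xi_other)))
  }
  optimal <- ifelse(factual <= counterfactual, received_arm, other_arm)
  data.frame(
    patient_id = arm_data$patient_id,
    received_arm = received_arm,
    factual_pred = factual,
    counterfactual_pred = counterfactual,
    optimal_arm = optimal,
    pai = abs(factual - counterfactual),
    received_optimal = factual <= counterfactual,
    observed_outcome = yr,
    stringsAsFactors = FALSE
  )
}

#' Cohort summaries of the Personalized Advantage Index
#'
#' Aggregates per-patient predictions into the standard PAI report:
#' mean PAI; the fraction of patients whose PAI reaches the clinically
#' meaningful threshold (default 5 PHQ-9 points); observed-outcome means
#' and counts split by whether the received treatment was the predicted
#' optimal one (an exact tie counts as optimal); and the mean absolute
#' error of the factual predictions against observed outcomes.
#'
#' @param preds output of [loo_predictions()] (both arms may be
#'   row-bound).
#' @param threshold PAI threshold in PHQ-9 points (default 5).
#' @return list of class `pai_summary`.
#' @export
summarize_pai <- function(preds, threshold = 5) {
  stopifnot(nrow(preds) > 0, !anyNA(preds$observed_outcome))
  opt <- preds$received_optimal
  structure(list(
    n = nrow(preds),
    mean_pai = mean(preds$pai),
    threshold = threshold,
    frac_pai_ge_threshold = mean(preds$pai >= threshold),
    n_optimal = sum(opt),
    n_suboptimal = sum(!opt),
    mean_observed_optimal = if (any(opt)) mean(preds$observed_outcome[opt]) else NA_real_,
    mean_observed_suboptimal = if (any(!opt)) mean(preds$observed_outcome[!opt]) else NA_real_,
    mean_absolute_error = mean(abs(preds$factual_pred - preds$observed_outcome))
  ), class = "pai_summary")
}

#' @export
print.pai_summary <- function(x, ...) {
  cat(sprintf("PAI summary over %d patients\n", x$n))
  cat(sprintf("  mean PAI: %.2f PHQ-9 points; PAI >= %g for %.1f%% of patients\n",
              x$mean_pai, x$threshold, 100 * x$frac_pai_ge_threshold))
  cat(sprintf("  observed outcome, optimal-received (n = %d): %.2f\n",
              x$n_optimal, x$mean_observed_optimal))
  cat(sprintf("  observed outcome, suboptimal-received (n = %d): %.2f\n",
              x$n_suboptimal, x$mean_observed_suboptimal))
  cat(sprintf("  mean |factual - observed| prediction error: %.2f\n",
              x$mean_absolute_error))
  invisible(x)
}
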