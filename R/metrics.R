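#' Binary classification metrics
#'
#' Thresholds the scores at `threshold` (predicted positive when
#' `score >= threshold`) and reports accuracy (ACC), specificity (SP),
#' sensitivity (SE), F1, and the rank-based AUC: the probability that a
#' random positive outscores a random negative, ties counted one half
#' (Mann-Whitney form, identical to trapezoidal ROC-AUC).
#'
#' @param y_true binary ground truth: logical, 0/1 numeric, or a factor /
#'   character vector together with `positive`.
#' @param y_score numeric scores (higher = more positive).
#' @param threshold decision threshold on the score.
#' @param positive the label counted as positive when `y_true` is not
#'   already 0/1.
#' @return a `classification_report` list with `ACC`, `SP`, `SE`, `F1`,
#'   `AUC`, `auc_defined`, and `confusion` (a `TP/TN/FP/FN` list).
#'   With single-class truth AUC is `NA` and `auc_defined` is `FALSE`;
#'   the confusion-based metrics are still returned (undefined ratios as
#'   `NaN`).
#' @export
classification_metrics <- function(y_true, y_score, threshold = 0.5,
                                   positive = NULL) {
  y <- as_binary_truth(y_true, positive)
  stopifnot(length(y) == length(y_score))
  pred <- as.integer(y_score >= threshold)
  TP <- sum(pred == 1 & y == 1)
  TN <- sum(pred == 0 & y == 0)
  FP <- sum(pred == 1 & y == 0)
  FN <- sum(pred == 0 & y == 1)
  npos <- sum(y == 1); nneg <- sum(y == 0)
  auc_defined <- npos > 0 && nneg > 0
  AUC <- if (auc_defined) {
    r <- rank(y_score)
    (sum(r[y == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
  } else NA_real_
  structure(list(
    ACC = (TP + TN) / (TP + TN + FP + FN),
    SP = TN / (TN + FP),
    SE = TP / (TP + FN),
    F1 = 2 * TP / (2 * TP + FP + FN),
    AUC = AUC,
    auc_defined = auc_defined,
    confusion = list(TP = TP, TN = TN, FP = FP, FN = FN)
  ), class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("ACC %.3f  SP %.3f  SE %.3f  F1 %.3f  AUC %s\n",
              x$ACC, x$SP, x$SE, x$F1,
              if (x$auc_defined) sprintf("%.3f", x$AUC) else "NA"))
  invisible(x)
}

#' Regression metrics with fold-error rates
#'
#' Reports the coefficient of determination R^2 (`1 - SS_res/SS_tot`),
#' MAE, RMSE, Pearson correlation, and fold-error rates. The per-sample
#' fold error is `fold_i = 1 + |yhat_i - y_i| / y_i` (so a perfect
#' prediction has fold 1); the rate at threshold k is the fraction of
#' samples with `fold_i < k` (strict), the usual success criterion for
#' energy-barrier prediction being fold < 2.
#'
#' @param y_true observed values, strictly positive (folds are undefined
#'   otherwise); an error names the offending ids.
#' @param y_pred predicted values.
#' @param fold_thresholds fold thresholds to report rates at.
#' @param ids optional ids used in error messages.
#' @return a `regression_report` list with `R2`, `MAE`, `RMSE`,
#'   `pearson_correlation`, `folds` (per sample), and `fold_rates`
#'   (named by threshold).
#' @export
regression_metrics <- function(y_true, y_pred, fold_thresholds = c(2, 3),
                               ids = NULL) {
  stopifnot(length(y_true) == length(y_pred))
  if (any(y_true <= 0 | !is.finite(y_true))) {
    bad <- which(y_true <= 0 | !is.finite(y_true))
    labs <- if (!is.null(ids)) ids[bad] else bad
    stop("y_true must be strictly positive; offending: ",
         paste(head(labs, 10), collapse = ", "))
  }
  res <- y_true - y_pred
  R2 <- 1 - sum(res^2) / sum((y_true - mean(y_true))^2)
  folds <- 1 + abs(y_pred - y_true) / y_true
  rates <- vapply(fold_thresholds, function(k) mean(folds < k), 0)
  names(rates) <- paste0("fold", fold_thresholds)
  structure(list(
    R2 = R2,
    MAE = mean(abs(res)),
    RMSE = sqrt(mean(res^2)),
    pearson_correlation = if (sd(y_pred) > 0) cor(y_true, y_pred) else NA_real_,
    folds = folds,
    fold_rates = rates
  ), class = "regression_report")
}

#' @export
print.regression_report <- function(x, ...) {
  cat(sprintf("R2 %.3f  MAE %.3f  RMSE %.3f  r %.3f  %s\n",
              x$R2, x$MAE, x$RMSE, x$pearson_correlation,
              paste(sprintf("%s-rate %.3f", names(x$fold_rates), x$fold_rates),
                    collapse = "  ")))
  invisible(x)
}

#' Barrier feasibility of the excited-state proton transfer
#'
#' An ESIPT process with a predicted activation barrier above roughly
#' 15-20 kcal/mol is considered unable to occur; a barrier at or below
#' the cutoff is feasible (closed boundary).
#'
#' @param barrier barrier(s) in kcal/mol, finite.
#' @param cutoff feasibility cutoff in kcal/mol, conventionally within
#'   `[15, 20]` (default 15).
#' @return character vector, `"feasible"` or `"infeasible"`.
#' @export
barrier_feasibility <- function(barrier, cutoff = 15) {
  stopifnot(all(is.finite(barrier)), cutoff >= 15, cutoff <= 20)
  ifelse(barrier <= cutoff, "feasible", "infeasible")
}

# Coerce assorted truth encodings to 0/1.
as_binary_truth <- function(y, positive = NULL) {
  if (is.logical(y)) return(as.integer(y))
  if (is.numeric(y) && all(y %in% c(0, 1))) return(as.integer(y))
  y <- as.character(y)
  if (is.null(positive)) {
    if ("ESIPT" %in% y) positive <- "ESIPT"
    else stop("supply `positive` for non-binary truth labels")
  }
  as.integer(y == positive)
}
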