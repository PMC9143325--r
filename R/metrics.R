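# Binary-classification evaluation: the 2x2 confusion matrix, the derived
# SE/SP/ACC/MCC set, and rank-based (Mann-Whitney) AUC.

#' Confusion matrix from hard predictions
#'
#' Standard 2x2 cross-tabulation with positive class 1.
#'
#' @param y_true,y_pred binary vectors of equal length.
#' @return object of class `confusion_matrix` with fields `TP, FP, TN, FN`.
#' @export
confusion_from_predictions <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stopf("prediction length mismatch")
  if (!all(y_true %in% c(0, 1)) || !all(y_pred %in% c(0, 1)))
    stopf("labels and predictions must be binary 0/1")
  confusion_matrix(TP = sum(y_true == 1 & y_pred == 1),
                   FP = sum(y_true == 0 & y_pred == 1),
                   TN = sum(y_true == 0 & y_pred == 0),
                   FN = sum(y_true == 1 & y_pred == 0))
}

#' @rdname confusion_from_predictions
#' @param TP,FP,TN,FN non-negative integer cell counts.
#' @export
confusion_matrix <- function(TP, FP, TN, FN) {
  cells <- c(TP = TP, FP = FP, TN = TN, FN = FN)
  if (any(cells < 0) || any(cells != floor(cells))) stopf("cells must be non-negative integers")
  if (sum(cells) == 0) stopf("empty confusion matrix")
  structure(as.list(cells), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> TP %d  FP %d  TN %d  FN %d\n", x$TP, x$FP, x$TN, x$FN))
  invisible(x)
}

#' Classification metrics from a confusion matrix
#'
#' Computes the standard set:
#' \deqn{ACC = (TP + TN) / (TP + FP + TN + FN)}
#' \deqn{SE = TP / (TP + FN), \quad SP = TN / (TN + FP)}
#' \deqn{MCC = \frac{TP \cdot TN - FP \cdot FN}{\sqrt{(FP+TN)(FP+TP)(FN+TN)(FN+TP)}}}
#' When any MCC denominator factor is 0, MCC is reported as 0 with
#' `degenerate_mcc = TRUE`. When a class is absent, the corresponding rate is
#' `NA` with an undefined flag.
#'
#' @param cm a `confusion_matrix`.
#' @return object of class `metric_set`: `SE`, `SP`, `ACC` in `[0, 1]`,
#'   `MCC` in `[-1, 1]`, plus flags.
#' @examples
#' classification_metrics(confusion_matrix(TP = 15, FP = 8, TN = 19, FN = 3))
#' @export
classification_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  TP <- cm$TP; FP <- cm$FP; TN <- cm$TN; FN <- cm$FN
  acc <- (TP + TN) / (TP + FP + TN + FN)
  se <- if (TP + FN > 0) TP / (TP + FN) else NA_real_
  sp <- if (TN + FP > 0) TN / (TN + FP) else NA_real_
  denom <- prod(sqrt(c(FP + TN, FP + TP, FN + TN, FN + TP)))
  degenerate <- denom == 0
  mcc <- if (degenerate) 0 else (TP * TN - FP * FN) / denom
  structure(list(SE = se, SP = sp, ACC = acc, MCC = mcc, AUC = NA_real_,
                 degenerate_mcc = degenerate,
                 se_undefined = is.na(se), sp_undefined = is.na(sp)),
            class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf("<metric_set> SE %.1f%%  SP %.1f%%  ACC %.1f%%  MCC %.3f  AUC %s\n",
              100 * x$SE, 100 * x$SP, 100 * x$ACC, x$MCC,
              if (is.na(x$AUC)) "-" else sprintf("%.3f", x$AUC)))
  invisible(x)
}

#' Format a metric set the way the result tables print it
#'
#' Percentages to 1 decimal place, MCC and AUC to 3.
#'
#' @param x a `metric_set`.
#' @return named character vector.
#' @export
format_metrics <- function(x) {
  stopifnot(inherits(x, "metric_set"))
  c(SE = sprintf("%.1f", round_half_up(100 * x$SE, 1)),
    SP = sprintf("%.1f", round_half_up(100 * x$SP, 1)),
    ACC = sprintf("%.1f", round_half_up(100 * x$ACC, 1)),
    MCC = sprintf("%.3f", round_half_up(x$MCC, 3)),
    AUC = if (is.na(x$AUC)) "" else sprintf("%.3f", round_half_up(x$AUC, 3)))
}

#' Rank-based AUC (Mann-Whitney formulation)
#'
#' Fraction of (positive, negative) pairs in which the positive scores
#' higher; ties count 0.5. Invariant under strictly monotone transforms of
#' the scores.
#'
#' @param y_true binary labels containing both classes.
#' @param scores numeric prediction scores.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(y_true, scores) {
  if (length(y_true) != length(scores)) stopf("score length mismatch")
  if (!all(y_true %in% c(0, 1))) stopf("labels must be binary 0/1")
  n1 <- sum(y_true == 1); n0 <- sum(y_true == 0)
  if (n1 == 0 || n0 == 0) stopf("AUC needs both classes present")
  r <- rank(scores, ties.method = "average")
  (sum(r[y_true == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
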