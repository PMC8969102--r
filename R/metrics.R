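# Evaluation metrics. The dementia (AD) class is the positive one.

#' Classification metrics with AD as the positive class
#'
#' Accuracy, precision, recall, F1 and specificity (TN / (TN + FP)), all as
#' percentages. A metric whose denominator is zero is reported as 0 with a
#' warning.
#'
#' @param predLabels predicted 0/1 labels (1 = AD).
#' @param trueLabels true 0/1 labels.
#' @return named numeric vector: accuracy, precision, recall, f1,
#'   specificity (percent).
#' @export
evaluateClassification <- function(predLabels, trueLabels) {
  if (length(predLabels) == 0L) stop("empty input")
  if (length(predLabels) != length(trueLabels)) stop("length mismatch")
  if (!all(predLabels %in% c(0, 1)) || !all(trueLabels %in% c(0, 1))) {
    stop("labels must be binary 0/1")
  }
  tp <- sum(predLabels == 1 & trueLabels == 1)
  tn <- sum(predLabels == 0 & trueLabels == 0)
  fp <- sum(predLabels == 1 & trueLabels == 0)
  fn <- sum(predLabels == 0 & trueLabels == 1)
  safe <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator); reported as 0")
      return(0)
    }
    num / den
  }
  precision <- safe(tp, tp + fp, "precision")
  recall <- safe(tp, tp + fn, "recall")
  f1 <- if (precision + recall == 0) {
    warning("f1 undefined (zero denominator); reported as 0")
    0
  } else 2 * precision * recall / (precision + recall)
  c(accuracy = 100 * (tp + tn) / length(trueLabels),
    precision = 100 * precision,
    recall = 100 * recall,
    f1 = 100 * f1,
    specificity = 100 * safe(tn, tn + fp, "specificity"))
}

#' Root mean squared error
#'
#' @param preds predicted values.
#' @param targets true values.
#' @return RMSE.
#' @export
evaluateRegression <- function(preds, targets) {
  if (length(preds) == 0L) stop("empty input")
  if (length(preds) != length(targets)) stop("length mismatch")
  sqrt(mean((preds - targets)^2))
}
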