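# Binary-classification metric suite: confusion counts, the five
# confusion-derived metrics, and AUROC for the positive class.

#' Confusion counts for binary injury labels
#'
#' @param predictions character/factor vector of "positive"/"negative"
#' @param truth ground-truth labels, same length
#' @return object of class `confusion_counts` with fields TP, TN, FP, FN
#' @export
confusion <- function(predictions, truth) {
  predictions <- as.character(predictions)
  truth <- as.character(truth)
  if (length(predictions) != length(truth)) {
    stop_with("efastcnn_invalid_argument",
              "predictions and truth must have equal length")
  }
  ok <- c("positive", "negative")
  if (!all(predictions %in% ok) || !all(truth %in% ok)) {
    stop_with("efastcnn_invalid_argument",
              "labels must be 'positive' or 'negative'")
  }
  structure(list(
    TP = sum(predictions == "positive" & truth == "positive"),
    TN = sum(predictions == "negative" & truth == "negative"),
    FP = sum(predictions == "positive" & truth == "negative"),
    FN = sum(predictions == "negative" & truth == "positive")
  ), class = "confusion_counts")
}

#' Confusion-derived performance metrics
#'
#' Accuracy `(TN+TP)/(TP+TN+FP+FN)`, precision `TP/(TP+FP)`, recall
#' (sensitivity) `TP/(TP+FN)`, specificity `TN/(TN+FP)` and F1
#' `2*recall*precision/(recall+precision)`. A metric whose denominator is
#' zero is returned as `NA` (flagged undefined), never an error.
#'
#' @param c a `confusion_counts` object (or list with TP/TN/FP/FN)
#' @return object of class `metric_set`; AUROC is filled in separately by
#'   [compute_auroc()]
#' @export
compute_metrics <- function(c) {
  total <- c$TP + c$TN + c$FP + c$FN
  if (total <= 0) {
    stop_with("efastcnn_invalid_argument", "no evaluated frames")
  }
  frac <- function(num, den) if (den > 0) num / den else NA_real_
  precision <- frac(c$TP, c$TP + c$FP)
  recall <- frac(c$TP, c$TP + c$FN)
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * recall * precision / (recall + precision)
  } else NA_real_
  structure(list(
    accuracy = (c$TN + c$TP) / total,
    precision = precision,
    recall = recall,
    specificity = frac(c$TN, c$TN + c$FP),
    f1 = f1,
    auroc = NA_real_
  ), class = "metric_set")
}

#' Area under the ROC curve for the positive class
#'
#' Tie-corrected Mann–Whitney probability that a random positive outscores a
#' random negative (ties count one half), which equals the trapezoidal area
#' under the empirical ROC curve.
#'
#' @param scores numeric positive-class scores
#' @param truth "positive"/"negative" labels
#' @return AUROC in `[0, 1]`
#' @export
compute_auroc <- function(scores, truth) {
  truth <- as.character(truth)
  if (length(scores) != length(truth)) {
    stop_with("efastcnn_invalid_argument", "scores/truth length mismatch")
  }
  pos <- truth == "positive"
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) {
    stop_with("efastcnn_invalid_argument",
              "both classes must be present to compute AUROC")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
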