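# Confusion-matrix statistics for the binary benign/malignant task.
# Malignant is the positive class throughout.

#' Construct a binary confusion matrix
#'
#' Either pass the four cell counts directly, or label/prediction vectors
#' (factors or characters with levels "benign"/"malignant") to be tallied.
#'
#' @param TP,FP,FN,TN Nonnegative cell counts.
#' @param labels,predictions Alternative input: vectors of true and
#'   predicted classes; "malignant" is the positive class.
#' @return Object of class `swnet_confusion` with fields TP, FP, FN, TN.
#' @export
confusion_matrix <- function(TP = NULL, FP = NULL, FN = NULL, TN = NULL,
                             labels = NULL, predictions = NULL) {
  if (!is.null(labels)) {
    labels <- as.character(labels)
    predictions <- as.character(predictions)
    stopifnot(length(labels) == length(predictions))
    TP <- sum(labels == "malignant" & predictions == "malignant")
    FP <- sum(labels == "benign" & predictions == "malignant")
    FN <- sum(labels == "malignant" & predictions == "benign")
    TN <- sum(labels == "benign" & predictions == "benign")
  }
  cells <- c(TP = TP, FP = FP, FN = FN, TN = TN)
  if (any(!is.finite(cells)) || any(cells < 0))
    stop("confusion-matrix cells must be nonnegative counts")
  structure(as.list(cells), class = "swnet_confusion")
}

#' @export
print.swnet_confusion <- function(x, ...) {
  m <- matrix(c(x$TP, x$FN, x$FP, x$TN), 2, 2,
              dimnames = list(truth = c("malignant", "benign"),
                              predicted = c("malignant", "benign")))
  print(m)
  invisible(x)
}

.safe_ratio <- function(num, den, what) {
  if (den == 0) {
    warning(what, ": zero denominator; returning 0", call. = FALSE)
    return(0)
  }
  num / den
}

#' Confusion-matrix metrics
#'
#' `precision` = TP/(TP+FP), `recall` (sensitivity) = TP/(TP+FN),
#' `specificity` = TN/(TN+FP), `accuracy` = (TP+TN)/total. Zero
#' denominators yield 0 with a warning.
#'
#' @param cm A `swnet_confusion`.
#' @return Proportion in \[0, 1\].
#' @export
precision <- function(cm) .safe_ratio(cm$TP, cm$TP + cm$FP, "precision")

#' @rdname precision
#' @export
recall <- function(cm) .safe_ratio(cm$TP, cm$TP + cm$FN, "recall")

#' @rdname precision
#' @export
specificity <- function(cm) .safe_ratio(cm$TN, cm$TN + cm$FP, "specificity")

#' @rdname precision
#' @export
accuracy <- function(cm)
  .safe_ratio(cm$TP + cm$TN, cm$TP + cm$FP + cm$FN + cm$TN, "accuracy")

#' F1 score (harmonic mean of precision and recall)
#'
#' Computed as 2PR/(P+R); 0 when both arguments are 0. With precision 1 and
#' recall 0.9990 this gives 0.9995, i.e. 99.95 on the percent scale.
#'
#' @param precision,recall Proportions in \[0, 1\].
#' @return Proportion in \[0, 1\].
#' @export
f1_score <- function(precision, recall) {
  stopifnot(precision >= 0, precision <= 1, recall >= 0, recall <= 1)
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

#' Full metrics report from a confusion matrix
#'
#' @param cm A `swnet_confusion`.
#' @param percent Report on the percent scale as well.
#' @return Object of class `swnet_metrics`: list with precision, recall,
#'   specificity, f1, accuracy (proportions) and a `percent` vector.
#' @export
metrics_report <- function(cm, percent = TRUE) {
  p <- precision(cm); r <- recall(cm)
  out <- list(precision = p, recall = r, specificity = specificity(cm),
              f1 = f1_score(p, r), accuracy = accuracy(cm),
              confusion = cm)
  if (percent)
    out$percent <- vapply(out[c("precision", "recall", "specificity",
                                "f1", "accuracy")],
                          function(v) 100 * v, numeric(1))
  structure(out, class = "swnet_metrics")
}

#' @export
print.swnet_metrics <- function(x, ...) {
  cat(sprintf(
    "precision %.4f  recall %.4f  specificity %.4f  f1 %.4f  accuracy %.4f\n",
    x$precision, x$recall, x$specificity, x$f1, x$accuracy))
  invisible(x)
}
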