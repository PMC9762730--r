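# Binary evaluation indexes over a 2x2 confusion table:
#   TPR = TP/(TP+FN), Spe = TN/(TN+FP), FPR = FP/(FP+TN),
#   FNR = FN/(TP+FN), Accuracy = (TP+TN)/(TP+TN+FP+FN).
# A ratio with a zero denominator is reported as NA (an explicit sentinel),
# never silently 0.

#' Tally a 2x2 confusion table
#'
#' @param predicted,truth Equal-length label vectors from a two-class set.
#' @param positive_label The label counted as positive (clinically, the
#'   Class1 diagnosis).
#' @return A `confusion_counts` object with fields `TP`, `FN`, `TN`, `FP`.
#' @export
#' @examples
#' confusion_counts(c("a", "b", "a"), c("a", "a", "a"), positive_label = "a")
confusion_counts <- function(predicted, truth, positive_label) {
  if (length(predicted) != length(truth) || length(truth) < 1L)
    stop("length mismatch: predicted and truth must have equal length >= 1")
  if (length(unique(truth)) > 2L)
    stop("not binary: more than 2 distinct truth labels")
  p <- predicted == positive_label
  t <- truth == positive_label
  structure(list(TP = sum(p & t), FN = sum(!p & t),
                 TN = sum(!p & !t), FP = sum(p & !t)),
            class = "confusion_counts")
}

#' Compute the five evaluation indexes
#'
#' @param counts A `confusion_counts` object (or list with `TP`, `FN`, `TN`,
#'   `FP`).
#' @return A `metrics_report` with `tpr`, `spe`, `fpr`, `fnr`, `accuracy`
#'   (each in `[0, 1]` or `NA` when its denominator is zero) and the input
#'   `counts`.
#' @export
#' @examples
#' compute_metrics(list(TP = 9, FN = 1, TN = 8, FP = 2))
compute_metrics <- function(counts) {
  TP <- counts$TP; FN <- counts$FN; TN <- counts$TN; FP <- counts$FP
  stopifnot(all(c(TP, FN, TN, FP) >= 0))
  total <- TP + FN + TN + FP
  if (total < 1) stop("empty confusion table")
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  structure(list(
    tpr = ratio(TP, TP + FN),
    spe = ratio(TN, TN + FP),
    fpr = ratio(FP, FP + TN),
    fnr = ratio(FN, TP + FN),
    accuracy = (TP + TN) / total,
    counts = counts), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  f <- function(v) if (is.na(v)) "undef" else sprintf("%.4f", v)
  cat(sprintf("TPR %s  Spe %s  FPR %s  FNR %s  Accuracy %s\n",
              f(x$tpr), f(x$spe), f(x$fpr), f(x$fnr), f(x$accuracy)))
  cat(sprintf("  (TP %d  FN %d  TN %d  FP %d)\n",
              x$counts$TP, x$counts$FN, x$counts$TN, x$counts$FP))
  invisible(x)
}
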