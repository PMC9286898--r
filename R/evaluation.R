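#' Confusion counts for binary predictions
#'
#' TP are pairs predicted positive that are truly positive, FP predicted
#' positive but truly negative, TN/FN the complements.  Swapping
#' `positive` to the other class swaps TP with TN and FP with FN.
#'
#' @param predicted predicted labels.
#' @param truth true labels; must be complete (no `NA`).
#' @param positive the label treated as the positive class.
#' @return an object of class `confusion_counts` (fields `TP`, `FP`, `TN`,
#'   `FN`).
#' @export
confusion_counts <- function(predicted, truth, positive = "positive") {
  if (length(predicted) != length(truth)) {
    stop("predicted and truth have different lengths")
  }
  if (anyNA(truth)) stop("truth labels contain NA")
  if (anyNA(predicted)) stop("predicted labels contain NA")
  predicted <- as.character(predicted)
  truth <- as.character(truth)
  positive <- as.character(positive)
  pp <- predicted == positive
  tp <- truth == positive
  structure(list(TP = sum(pp & tp), FP = sum(pp & !tp),
                 TN = sum(!pp & !tp), FN = sum(!pp & tp)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("TP=%d FP=%d TN=%d FN=%d\n", x$TP, x$FP, x$TN, x$FN))
  invisible(x)
}

safe_div <- function(num, den) if (den == 0) NA_real_ else num / den

#' Confusion-matrix classification metrics
#'
#' Computes accuracy `(TP+TN)/(TP+TN+FP+FN)`, precision `TP/(TP+FP)`,
#' sensitivity `TP/(TP+FN)`, F-measure `2TP/(2TP+FP+FN)` and the Matthews
#' correlation coefficient
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.
#' Metrics with a zero denominator are reported as `NA` (explicitly
#' undefined), never coerced to 0.
#'
#' @param counts a `confusion_counts` object.
#' @param legacy_mcc if `TRUE`, additionally return `mcc_legacy`, the
#'   unnormalized variant `(TP*TN - FP*FN) / ((TP+FP)(TP+FN)(TN+FN))` — a
#'   non-standard formula occasionally seen in print (no square root, factor
#'   `TN+FP` missing); provided for audit only.
#' @return named list with `acc`, `pre`, `sen`, `f_measure`, `mcc` (and
#'   optionally `mcc_legacy`).
#' @export
classification_metrics <- function(counts, legacy_mcc = FALSE) {
  stopifnot(inherits(counts, "confusion_counts"))
  # doubles: the MCC denominator overflows 32-bit integers at realistic n
  tp <- as.numeric(counts$TP); fp <- as.numeric(counts$FP)
  tn <- as.numeric(counts$TN); fn <- as.numeric(counts$FN)
  if (any(c(tp, fp, tn, fn) < 0)) stop("negative confusion counts")
  total <- tp + fp + tn + fn
  if (total == 0) stop("empty prediction set")
  out <- list(
    acc = safe_div(tp + tn, total),
    pre = safe_div(tp, tp + fp),
    sen = safe_div(tp, tp + fn),
    f_measure = safe_div(2 * tp, 2 * tp + fp + fn))
  mcc_den2 <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  out$mcc <- if (mcc_den2 == 0) NA_real_ else {
    (tp * tn - fp * fn) / sqrt(mcc_den2)
  }
  if (legacy_mcc) {
    den <- (tp + fp) * (tp + fn) * (tn + fn)
    out$mcc_legacy <- if (den == 0) NA_real_ else (tp * tn - fp * fn) / den
  }
  out
}

#' ROC curve points
#'
#' Full threshold sweep over the unique scores (predict positive when
#' `score >= threshold`), with `(0,0)` appended.
#'
#' @param scores numeric scores (higher = more positive).
#' @param truth true labels.
#' @param positive positive-class label.
#' @return data frame with `threshold`, `fpr`, `tpr`, one row per unique
#'   score plus the origin.
#' @export
roc_curve <- function(scores, truth, positive = "positive") {
  y <- as.character(truth) == as.character(positive)
  if (all(y) || !any(y)) stop("both classes must be present to compute ROC")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- y[ord]
  n1 <- sum(y); n0 <- sum(!y)
  tp <- cumsum(y); fp <- cumsum(!y)
  last <- !duplicated(s, fromLast = TRUE)   # one point per unique threshold
  data.frame(threshold = c(Inf, s[last]),
             fpr = c(0, fp[last] / n0),
             tpr = c(0, tp[last] / n1))
}

#' Area under the ROC curve
#'
#' Computed as the normalized Mann-Whitney U statistic with rank-averaged
#' ties, which equals the trapezoidal area under the full-sweep ROC curve of
#' [roc_curve()].  Tied scores between the classes contribute 1/2.
#'
#' @inheritParams roc_curve
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, truth, positive = "positive") {
  y <- as.character(truth) == as.character(positive)
  if (all(y) || !any(y)) stop("both classes must be present to compute AUC")
  r <- rank(scores)                     # ties.method = "average"
  n1 <- sum(y); n0 <- sum(!y)
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Full metric report for a prediction set
#'
#' Thresholds the probabilities (positive iff strictly greater than
#' `threshold`), computes the confusion counts and metrics with the positive
#' class as reference, the same metrics with the negative class treated as
#' positive (`per_class`), and the AUC.
#'
#' @param probabilities predicted positive-class probabilities.
#' @param truth true labels (`"positive"`/`"negative"` or 1/0).
#' @param threshold decision threshold (default 0.5, strict).
#' @return an object of class `metric_report`.
#' @export
metric_report <- function(probabilities, truth, threshold = 0.5) {
  truth <- as.character(truth)
  truth[truth %in% c("1", "TRUE")] <- "positive"
  truth[truth %in% c("0", "FALSE")] <- "negative"
  predicted <- ifelse(probabilities > threshold, "positive", "negative")
  counts <- confusion_counts(predicted, truth, positive = "positive")
  pos <- classification_metrics(counts)
  neg <- classification_metrics(
    confusion_counts(predicted, truth, positive = "negative"))
  structure(list(counts = counts,
                 acc = pos$acc, sen = pos$sen, pre = pos$pre,
                 f_measure = pos$f_measure, mcc = pos$mcc,
                 auc = roc_auc(probabilities, truth),
                 per_class = list(positive = pos, negative = neg),
                 threshold = threshold),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, digits = 3, ...) {
  cat(sprintf("Acc %.*f  Sen %.*f  Pre %.*f  F %.*f  MCC %.*f  AUC %.*f\n",
              digits, x$acc, digits, x$sen, digits, x$pre,
              digits, x$f_measure, digits, x$mcc, digits, x$auc))
  print(x$counts)
  invisible(x)
}

#' @export
as.data.frame.metric_report <- function(x, ...) {
  data.frame(acc = x$acc, sen = x$sen, pre = x$pre,
             f_measure = x$f_measure, mcc = x$mcc, auc = x$auc)
}

#' Relative improvement and relative drop, in percent
#'
#' `relative_improvement(new, baseline)` is `100 * (new - baseline) /
#' baseline`; `relative_drop(original, new)` is `100 * (original - new) /
#' original`.  Both are reported to 3 decimal places, the precision used for
#' the published model comparisons (e.g. sensitivity 0.956 vs 0.933 is a
#' 2.465% improvement).  These are relative differences, not
#' percentage-point differences.
#'
#' @param new,baseline,original metric values; the reference value must be
#'   strictly positive.
#' @return a percentage rounded to 3 decimals.
#' @export
relative_improvement <- function(new, baseline) {
  if (any(baseline <= 0)) stop("baseline must be > 0")
  round(100 * (new - baseline) / baseline, 3)
}

#' @rdname relative_improvement
#' @export
relative_drop <- function(original, new) {
  if (any(original <= 0)) stop("original must be > 0")
  round(100 * (original - new) / original, 3)
}
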