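#' @title Diagnostic evaluation
#' @description
#' Confusion-matrix metrics, ROC and precision-recall curves with AFib as
#' the positive class throughout. Counts are stored exactly; ratios are
#' kept at full precision and rounded only for display (3 decimal places).
#' @name evaluation
NULL

#' Confusion matrix from labels and predictions
#'
#' @param labels true binary rhythm labels (`AFib` / `non-AFib`); `noisy`
#'   must be mapped or removed upstream and is rejected here.
#' @param predictions predicted binary labels, same length.
#' @return A `confusion_matrix` with integer fields `tp`, `fn`, `fp`, `tn`.
#' @export
confusion <- function(labels, predictions) {
  if (length(labels) != length(predictions))
    stop("labels (", length(labels), ") and predictions (",
         length(predictions), ") differ in length")
  l <- as.character(labels)
  p <- as.character(predictions)
  bad <- setdiff(unique(c(l, p)), c(AFIB, NON_AFIB))
  if (length(bad))
    stop("non-binary symbol(s): ", paste(bad, collapse = ", "),
         "; map noisy labels upstream")
  confusion_counts(tp = sum(l == AFIB & p == AFIB),
                   fn = sum(l == AFIB & p == NON_AFIB),
                   fp = sum(l == NON_AFIB & p == AFIB),
                   tn = sum(l == NON_AFIB & p == NON_AFIB))
}

#' Confusion matrix from counts
#'
#' @param tp,fn,fp,tn non-negative integer counts (AFib positive).
#' @return A `confusion_matrix`.
#' @export
confusion_counts <- function(tp, fn, fp, tn) {
  counts <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  structure(stats::setNames(as.list(as.integer(counts)), names(counts)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2, byrow = TRUE,
              dimnames = list(truth = c("AFib", "non-AFib"),
                              predicted = c("AFib", "non-AFib")))
  print(m)
  invisible(x)
}

safe_ratio <- function(num, den) if (den == 0) NA_real_ else num / den

#' Diagnostic metrics from a confusion matrix
#'
#' @param cm a `confusion_matrix` (from [confusion()] or
#'   [confusion_counts()]).
#' @return A `metrics_report` list: `sensitivity`, `specificity`, `ppv`,
#'   `npv`, `f1`, plus the complementary error rates `fnr`
#'   (`1 - sensitivity`) and `fpr` (`1 - specificity`). Ratios with a zero
#'   denominator are the `NA` sentinel, never `NaN`.
#' @examples
#' metrics(confusion_counts(tp = 722, fn = 55, fp = 105, tn = 3762))
#' @export
metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  sens <- safe_ratio(cm$tp, cm$tp + cm$fn)
  spec <- safe_ratio(cm$tn, cm$tn + cm$fp)
  ppv <- safe_ratio(cm$tp, cm$tp + cm$fp)
  npv <- safe_ratio(cm$tn, cm$tn + cm$fn)
  f1 <- safe_ratio(2 * cm$tp, 2 * cm$tp + cm$fp + cm$fn)
  structure(list(sensitivity = sens, specificity = spec,
                 ppv = ppv, npv = npv, f1 = f1,
                 fnr = if (is.na(sens)) NA_real_ else 1 - sens,
                 fpr = if (is.na(spec)) NA_real_ else 1 - spec,
                 counts = cm),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 3, ...) {
  v <- unlist(x[c("sensitivity", "specificity", "ppv", "npv", "f1")])
  print(round(v, digits))
  invisible(x)
}

# threshold convention: predict AFib when score >= t; thresholds swept over
# the distinct scores plus a +Inf sentinel (no positive calls).
roc_points <- function(y, scores) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  yy <- y[ord]
  np <- sum(y)
  nn <- length(y) - np
  idx <- which(!duplicated(s, fromLast = TRUE))  # last index of each tie run
  ctp <- cumsum(yy)
  cfp <- cumsum(!yy)
  data.frame(threshold = c(Inf, s[idx]),
             tpr = c(0, ctp[idx] / np),
             fpr = c(0, cfp[idx] / nn))
}

#' ROC curve and AUC
#'
#' AUC by the trapezoidal rule over the full threshold sweep, which equals
#' the pairwise concordance probability
#' `P(s+ > s-) + 0.5 * P(s+ = s-)`.
#'
#' @param labels binary rhythm labels (`AFib` positive).
#' @param scores real-valued scores, higher meaning more AFib-like.
#' @return list with `auc` and `points` (`data.frame` of `threshold`,
#'   `fpr`, `tpr`).
#' @export
roc_auc <- function(labels, scores) {
  y <- as.character(labels) == AFIB
  if (length(y) != length(scores)) stop("length mismatch")
  if (all(y) || !any(y))
    stop("ROC needs at least one positive and one negative")
  pts <- roc_points(y, scores)
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) +
                                utils::tail(pts$tpr, -1)) / 2)
  list(auc = auc, points = pts)
}

#' Precision-recall curve
#'
#' Precision and recall at each distinct score threshold (predict AFib
#' when score >= t). A categorical-only algorithm contributes a single
#' operating point; see [operating_point()].
#'
#' @inheritParams roc_auc
#' @return `data.frame` with `threshold`, `recall`, `precision`.
#' @export
pr_curve <- function(labels, scores) {
  y <- as.character(labels) == AFIB
  if (length(y) != length(scores)) stop("length mismatch")
  if (all(y) || !any(y))
    stop("PR curve needs at least one positive and one negative")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  yy <- y[ord]
  idx <- which(!duplicated(s, fromLast = TRUE))
  ctp <- cumsum(yy)[idx]
  npred <- idx
  data.frame(threshold = s[idx],
             recall = ctp / sum(y),
             precision = ctp / npred)
}

#' Operating point of a categorical algorithm
#'
#' @param labels binary rhythm labels.
#' @param votes the algorithm's binary calls.
#' @return list with `sensitivity`, `specificity`, `precision`, `recall`.
#' @export
operating_point <- function(labels, votes) {
  m <- metrics(confusion(labels, votes))
  list(sensitivity = m$sensitivity, specificity = m$specificity,
       precision = m$ppv, recall = m$sensitivity)
}
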