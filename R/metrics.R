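#' Threshold-dependent classification metrics from confusion counts
#'
#' Computes sensitivity SE = TP/(TP+FN), specificity SP = TN/(TN+FP),
#' accuracy ACC = 100 * (TP+TN)/(TP+FP+TN+FN) and the Matthews correlation
#' coefficient MCC = (TP*TN - FP*FN) / sqrt((TN+FN)(TP+FN)(TN+FP)(TP+FP)).
#' A metric whose denominator is zero is undefined and reported as `NA`
#' (never an error), so fold-level aggregation can skip it.
#'
#' @param tp,fn,tn,fp Non-negative confusion counts. `tp` may also be a
#'   one-row data frame / list carrying all four counts.
#' @return One-row tibble: `se`, `sp` in \[0, 1\]; `acc_percent` in
#'   \[0, 100\]; `mcc` in \[-1, 1\]; plus `n_pos`, `n_neg`.
#' @export
#' @examples
#' confusion_metrics(tp = 3, fn = 1, tn = 2, fp = 2)
confusion_metrics <- function(tp, fn = NULL, tn = NULL, fp = NULL) {
  if (is.list(tp)) {
    c4 <- tp
    tp <- c4$tp; fn <- c4$fn; tn <- c4$tn; fp <- c4$fp
  }
  counts <- c(tp = tp, fn = fn, tn = tn, fp = fp)
  if (anyNA(counts) || any(counts < 0)) abort("confusion counts must be non-negative")
  if (sum(counts) == 0) abort("all confusion counts are zero")
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  mcc_den <- sqrt(prod(c(tn + fn, tp + fn, tn + fp, tp + fp)))
  tibble(
    se = safe_div(tp, tp + fn),
    sp = safe_div(tn, tn + fp),
    acc_percent = 100 * (tp + tn) / sum(counts),
    mcc = if (mcc_den > 0) (tp * tn - fp * fn) / mcc_den else NA_real_,
    n_pos = tp + fn,
    n_neg = tn + fp
  )
}

#' Confusion counts from scores and labels at a decision threshold
#'
#' @param scores Numeric scores in \[0, 1\].
#' @param labels Logical (or 0/1, or `"positive"`/`"negative"`) true labels.
#' @param threshold Scores `>= threshold` are called positive.
#' @return One-row tibble `tp`, `fn`, `tn`, `fp`.
#' @export
confusion_counts <- function(scores, labels, threshold = 0.5) {
  labels <- as_binary_labels(labels)
  if (length(scores) != length(labels)) abort("scores and labels differ in length")
  call_pos <- scores >= threshold
  tibble(
    tp = sum(call_pos & labels), fn = sum(!call_pos & labels),
    tn = sum(!call_pos & !labels), fp = sum(call_pos & !labels)
  )
}

#' Area under the ROC curve
#'
#' The ROC curve plots SE against 1 - SP over all decision thresholds; its
#' area is computed exactly by Mann-Whitney pair counting — the fraction of
#' (positive, negative) pairs where the positive scores higher, ties
#' counting one half — which equals trapezoidal integration of the
#' threshold-swept curve. 0.5 corresponds to a random predictor and 1 to a
#' perfect one. Both routes are implemented; `method = "rank"` (the
#' default) uses midranks, `"trapezoid"` integrates the empirical curve.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels True labels as for [confusion_counts()]; both classes must
#'   be present.
#' @param method `"rank"` or `"trapezoid"`.
#' @return A single number in \[0, 1\].
#' @export
#' @examples
#' roc_auc(c(0.9, 0.8, 0.4, 0.3), c(TRUE, FALSE, TRUE, FALSE))
roc_auc <- function(scores, labels, method = c("rank", "trapezoid")) {
  method <- match.arg(method)
  labels <- as_binary_labels(labels)
  if (length(scores) != length(labels)) abort("scores and labels differ in length")
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) abort("both classes must be present to compute AUC")
  if (method == "rank") {
    r <- rank(scores, ties.method = "average")
    (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  } else {
    pts <- roc_points(scores, labels)
    x <- 1 - pts$sp; y <- pts$se # already in ascending FPR order
    sum(diff(x) * (head(y, -1) + y[-1]) / 2)
  }
}

#' ROC curve points over all distinct thresholds
#'
#' @inheritParams roc_auc
#' @return Tibble with one row per threshold (plus the two endpoints):
#'   `threshold`, `se`, `sp`. Suitable for plotting SE vs 1 - SP.
#' @export
roc_points <- function(scores, labels) {
  labels <- as_binary_labels(labels)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) abort("both classes must be present")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tibble(
    threshold = thr,
    se = vapply(thr, function(t) sum(scores >= t & labels) / n_pos, 0),
    sp = vapply(thr, function(t) sum(scores < t & !labels) / n_neg, 0)
  )
}

as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) abort("numeric labels must be 0/1")
    return(labels == 1)
  }
  x <- tolower(as.character(labels))
  if (all(x %in% c("positive", "negative"))) return(x == "positive")
  if (all(x %in% c("pos", "neg"))) return(x == "pos")
  if (all(x %in% c("y", "n"))) return(x == "y")
  abort("labels must be logical, 0/1, or positive/negative strings")
}
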