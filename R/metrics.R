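#' Area under the ROC curve (exact pairwise form)
#'
#' The probability that a random positive is ranked above a random
#' negative, with ties counted 1/2: the normalized sum over all
#' positive-negative pairs of `I(s_i > t_j) + 0.5 I(s_i = t_j)`.  Computed
#' through midranks, which is algebraically identical to the double loop.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 labels, same length.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels) {
  labels <- as.integer(labels)
  M <- sum(labels == 1); N <- sum(labels == 0)
  if (M == 0 || N == 0) stop("AUC needs both classes present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - M * (M + 1) / 2) / (M * N)
}

#' Average precision by the trapezoidal rule
#'
#' Approximates the area under the precision-recall curve with trapezoids
#' between consecutive thresholds, one threshold at each distinct score in
#' descending order, the curve anchored at `(recall 0, precision 1)`.
#' This is the trapezoidal PR area -- deliberately distinct from the
#' step-wise average precision of common toolkits, and invariant under
#' strictly monotone transforms of the scores.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 labels, same length.
#' @return AP in `[0, 1]`.
#' @export
ap_score <- function(scores, labels) {
  labels <- as.integer(labels)
  M <- sum(labels == 1); N <- sum(labels == 0)
  if (M == 0 || N == 0) stop("AP needs both classes present")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  n <- length(s)
  bound <- c(which(diff(s) != 0), n)   # last index at each distinct score
  tp <- cumsum(y)[bound]
  P <- tp / bound
  R <- tp / M
  P0 <- c(1, P[-length(P)])
  R0 <- c(0, R[-length(R)])
  sum((R - R0) * (P + P0) / 2)
}

#' Precision, recall and F1 at a probability threshold
#'
#' `P = TP/(TP+FP)`, `R = TP/(TP+FN)`, `F1 = 2PR/(P+R)`.  When no positive
#' predictions are made, precision is reported as 0 with a warning; an
#' all-zero denominator for F1 likewise yields 0.
#'
#' @param probs predicted probabilities.
#' @param labels 0/1 labels.
#' @param threshold classification threshold (default 0.5; prediction is
#'   positive when `probs >= threshold`).
#' @return Named list `precision`, `recall`, `f1`, `tp`, `tn`, `fp`, `fn`.
#' @export
precision_recall_f1 <- function(probs, labels, threshold = 0.5) {
  labels <- as.integer(labels)
  pred <- as.integer(probs >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  tn <- sum(pred == 0 & labels == 0)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  if (tp + fp == 0) {
    warning("no positive predictions; precision reported as 0",
            call. = FALSE)
    precision <- 0
  } else precision <- tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f1 = f1,
       tp = tp, tn = tn, fp = fp, fn = fn)
}
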