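#' Binary classification metrics with a threshold-free AUC
#'
#' Accuracy, sensitivity and specificity are computed at the given score
#' threshold (predicted positive when score >= threshold, with class 1 the
#' positive class). The AUC is the pairwise concordance
#' \deqn{AUC = (\#\{s_p > s_n\} + 0.5\,\#\{s_p = s_n\}) / (P \cdot N)}
#' over all positive/negative score pairs, computed via midranks. ROC
#' points are generated by sweeping the threshold over the unique scores;
#' the curve starts at (0, 0) and ends at (1, 1) with both coordinates
#' non-decreasing.
#'
#' @param truth binary vector (0/1 or logical).
#' @param scores numeric scores, higher = more positive.
#' @param threshold decision threshold for ACC/SEN/SPE (default 0.5).
#' @return list with `acc`, `sen`, `spe`, `auc` and `roc` (data.frame with
#'   columns fpr, tpr).
#' @examples
#' compute_binary_metrics(c(1, 0, 1, 0), c(0.6, 0.6, 0.4, 0.2))$auc  # 0.625
#' @export
compute_binary_metrics <- function(truth, scores, threshold = 0.5) {
  truth <- as.integer(truth)
  if (length(truth) != length(scores))
    stop_invalid("truth and scores must have equal length")
  if (!all(truth %in% c(0L, 1L)))
    stop_invalid("truth must be binary (0/1)")
  pos <- truth == 1L
  npos <- sum(pos); nneg <- sum(!pos)
  if (npos == 0 || nneg == 0)
    stop_invalid("AUC undefined: truth contains a single class")

  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & truth == 1); tn <- sum(pred == 0 & truth == 0)
  fp <- sum(pred == 1 & truth == 0); fn <- sum(pred == 0 & truth == 1)

  # midrank (Mann-Whitney) form of the concordance count
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[pos]) - npos * (npos + 1) / 2) / (npos * nneg)

  ord <- order(scores, decreasing = TRUE)
  ts <- truth[ord]; ss <- scores[ord]
  cum_tp <- cumsum(ts); cum_fp <- cumsum(1 - ts)
  last <- !duplicated(ss, fromLast = TRUE)  # group tied scores
  roc <- data.frame(fpr = c(0, cum_fp[last] / nneg),
                    tpr = c(0, cum_tp[last] / npos))

  list(acc = (tp + tn) / length(truth),
       sen = tp / (tp + fn),
       spe = tn / (tn + fp),
       auc = auc,
       roc = roc)
}

#' Negative-to-positive class ratio
#'
#' The imbalance ratio used for the gradient-boosted trees'
#' `scale_pos_weight` option: number of negative samples divided by the
#' number of positive samples, rounded to two decimals.
#'
#' @param labels binary vector (1 = positive).
#' @return scalar ratio, 2-decimal precision.
#' @examples
#' imbalance_ratio(rep(c(0, 1), c(112, 41)))  # 2.73
#' @export
imbalance_ratio <- function(labels) {
  labels <- as.integer(labels)
  npos <- sum(labels == 1L)
  if (npos == 0) stop_invalid("imbalance ratio undefined: no positive labels")
  round(sum(labels == 0L) / npos, 2)
}
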