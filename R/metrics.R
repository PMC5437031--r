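# Classification metrics: confusion counts at a probability threshold,
# overall accuracy (Q), sensitivity (SE), specificity (SP) as percentages,
# and AUC via the Mann-Whitney rank statistic (ties counted half).

#' Confusion-matrix metrics and AUC
#'
#' Q = 100*(TP+TN)/(TP+TN+FN+FP), SE = 100*TP/(TP+FN),
#' SP = 100*TN/(TN+FP). The positive class (carcinogen) is label 1; a
#' compound is called positive when its probability reaches the threshold.
#' AUC is the probability that a random positive is ranked above a random
#' negative (tied probabilities count 1/2) and is returned as a fraction in
#' [0, 1]; cross-validation summaries report it multiplied by 100 to line
#' up with the percentage metrics.
#'
#' @param y_true 0/1 labels.
#' @param y_prob predicted probabilities of the positive class.
#' @param threshold decision cutoff (default 0.5, reached-or-exceeded is
#'   positive).
#' @return one-row data.frame: TP, TN, FP, FN, Q, SE, SP, AUC. With a
#'   single-class `y_true` the AUC is NA (with a warning); the other
#'   metrics are still returned.
#' @export
computeMetrics <- function(y_true, y_prob, threshold = 0.5) {
  y_true <- as.integer(y_true)
  stopifnot(length(y_true) == length(y_prob), length(y_true) > 0,
            all(y_true %in% c(0L, 1L)), all(is.finite(y_prob)))
  pred <- as.integer(y_prob >= threshold)
  TP <- sum(pred == 1L & y_true == 1L)
  TN <- sum(pred == 0L & y_true == 0L)
  FP <- sum(pred == 1L & y_true == 0L)
  FN <- sum(pred == 0L & y_true == 1L)
  Q <- 100 * (TP + TN) / length(y_true)
  SE <- if (TP + FN > 0) 100 * TP / (TP + FN) else NA_real_
  SP <- if (TN + FP > 0) 100 * TN / (TN + FP) else NA_real_
  AUC <- aucRank(y_true, y_prob)
  data.frame(TP = TP, TN = TN, FP = FP, FN = FN,
             Q = Q, SE = SE, SP = SP, AUC = AUC)
}

#' Rank-statistic AUC
#'
#' Mann-Whitney formulation: with ranks r of the pooled probabilities,
#' AUC = (sum of positive ranks - n_pos*(n_pos+1)/2) / (n_pos * n_neg).
#' Average ranks give tied pairs a weight of 1/2, matching exhaustive pair
#' counting.
#'
#' @param y_true 0/1 labels.
#' @param y_prob probabilities or scores.
#' @return AUC in [0, 1]; NA with a warning when a class is absent.
#' @export
aucRank <- function(y_true, y_prob) {
  y_true <- as.integer(y_true)
  npos <- sum(y_true == 1L)
  nneg <- sum(y_true == 0L)
  if (npos == 0L || nneg == 0L) {
    warning("AUC undefined: only one class present")
    return(NA_real_)
  }
  r <- rank(y_prob)
  (sum(r[y_true == 1L]) - npos * (npos + 1) / 2) / (npos * nneg)
}
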