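# Classification / regression metrics used by train_eval. ROC AUC is
# delegated to pROC; the precision-recall area has no installed provider
# and is computed here by step integration (average precision).

roc_auc <- function(labels, scores) {
  if (length(unique(labels)) < 2L) return(NA_real_)
  as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                 direction = "<", levels = c(0, 1))))
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-integrates precision over recall at every score threshold:
#' `sum_i (R_i - R_{i-1}) * P_i`, descending-score order with ties
#' collapsed.
#'
#' @param labels 0/1 vector.
#' @param scores numeric scores, larger = more positive.
#' @return scalar in (0, 1].
#' @export
pr_auc <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  npos <- sum(labels == 1)
  if (npos == 0L) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  l <- labels[ord]
  s <- scores[ord]
  tp <- cumsum(l == 1)
  fp <- cumsum(l == 0)
  keep <- c(s[-1] != s[-length(s)], TRUE) # last index of each tie block
  tp <- tp[keep]; fp <- fp[keep]
  precision <- tp / (tp + fp)
  recall <- tp / npos
  sum(diff(c(0, recall)) * precision)
}

confusion_metrics <- function(labels, pred) {
  tp <- sum(labels == 1 & pred == 1)
  fp <- sum(labels == 0 & pred == 1)
  fn <- sum(labels == 1 & pred == 0)
  tn <- sum(labels == 0 & pred == 0)
  list(confusion = matrix(c(tn, fn, fp, tp), 2, 2,
                          dimnames = list(predicted = c("0", "1"),
                                          actual = c("0", "1"))),
       precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_)
}
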