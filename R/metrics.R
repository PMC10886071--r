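## Ranking and multi-label classification metrics.

#' Area under the ROC curve
#'
#' The probability that a uniformly random positive outscores a uniformly
#' random negative, with ties counting one half (the rank-statistic form
#' of the Wilcoxon/Mann-Whitney estimator).
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 labels; both classes must be present.
#' @return AUROC in [0, 1].
#' @export
auroc <- function(scores, labels) {
  checkTwoClass(scores, labels)
  pos <- labels == 1
  r <- rank(scores, ties.method = "average")
  nPos <- sum(pos); nNeg <- sum(!pos)
  (sum(r[pos]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Area under the precision-recall curve
#'
#' Step integral of precision over recall across the descending-score
#' threshold sweep (the average-precision form): `sum_i (R_i - R_{i-1})
#' P_i` over distinct score thresholds.
#'
#' @inheritParams auroc
#' @return AUPR in (0, 1].
#' @export
aupr <- function(scores, labels) {
  checkTwoClass(scores, labels)
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  s <- scores[ord]
  tp <- cumsum(y)
  fp <- cumsum(1 - y)
  ## evaluate at each distinct threshold (last index of each tied block)
  last <- which(s != c(s[-1], NA) | seq_along(s) == length(s))
  tp <- tp[last]; fp <- fp[last]
  prec <- tp / (tp + fp)
  rec <- tp / sum(labels == 1)
  dRec <- diff(c(0, rec))
  sum(dRec * prec)
}

checkTwoClass <- function(scores, labels) {
  if (length(scores) != length(labels))
    stop("scores and labels must have the same length")
  if (!all(labels %in% c(0, 1)))
    stop("labels must be 0/1")
  if (length(unique(labels)) < 2L)
    stop("both classes must be present to compute a ranking metric")
  invisible(TRUE)
}

#' Micro-averaged F1 score
#'
#' Pools every (sample, label) decision at the threshold before computing
#' F1, the convention for multi-label protein-interaction evaluation.
#' Missing labels (`NA`) are excluded from the pool.
#'
#' @param probs numeric vector or matrix of probabilities.
#' @param labels 0/1 vector or matrix of the same shape.
#' @param threshold decision threshold (default 0.5; predictions `>=`
#'   threshold count positive).
#' @return micro-F1 in [0, 1].
#' @export
microF1 <- function(probs, labels, threshold = 0.5) {
  if (length(probs) != length(labels))
    stop("probs and labels must have the same shape")
  keep <- !is.na(labels)
  p <- probs[keep] >= threshold
  y <- labels[keep] == 1
  tp <- sum(p & y)
  fp <- sum(p & !y)
  fn <- sum(!p & y)
  if (tp + fp + fn == 0) return(1)
  2 * tp / (2 * tp + fp + fn)
}
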