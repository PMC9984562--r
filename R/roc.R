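#' ROC analysis of a score against binary labels
#'
#' Sweeps the classifier "score >= t" over all observed score values,
#' records TPR and FPR, integrates the AUC by the trapezoidal rule over the
#' full curve (anchored at (0,0) and (1,1)), and selects the Youden-optimal
#' threshold: the score value maximizing TPR - FPR, taking the smallest such
#' threshold on ties.
#'
#' @param scores numeric vector.
#' @param labels logical (or 0/1) vector; `TRUE` marks the positive class.
#' @return An object of class `roc_result`: `$thresholds`, `$tpr`, `$fpr`
#'   (ordered by decreasing threshold), `$auc`, `$youden_j`,
#'   `$youden_threshold`.
#' @export
roc_analysis <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.logical(labels)
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0)
    stop("ROC analysis needs both classes present")
  thr <- sort(unique(scores), decreasing = TRUE)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; l <- labels[o]
  cum_tp <- cumsum(l); cum_fp <- cumsum(!l)
  # index of the last observation with score >= each threshold
  last <- length(s) - match(thr, rev(s)) + 1L
  tpr <- cum_tp[last] / n_pos
  fpr <- cum_fp[last] / n_neg
  x <- c(0, fpr, 1); y <- c(0, tpr, 1)
  auc <- sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  j <- tpr - fpr
  best <- which(j == max(j))
  youden_threshold <- min(thr[best])
  structure(list(thresholds = thr, tpr = tpr, fpr = fpr, auc = auc,
                 youden_j = max(j), youden_threshold = youden_threshold,
                 n_pos = n_pos, n_neg = n_neg),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "roc_result: AUC = %.4f, Youden J = %.4f at threshold %.6g (%d pos / %d neg)\n",
    x$auc, x$youden_j, x$youden_threshold, x$n_pos, x$n_neg))
  invisible(x)
}
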