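#' Binary classification metrics
#'
#' Thresholded metrics (accuracy, precision, recall, F1, confusion counts)
#' at `threshold`, plus AUROC by the Mann-Whitney pair-counting formulation
#' (ties credited 1/2) and AUPRC as the step integral of the
#' precision-recall curve (no interpolation). With a single-class label
#' vector, AUROC and AUPRC are reported as `NA` while threshold metrics are
#' still computed.
#'
#' @param scores Numeric prediction scores in \[0, 1\].
#' @param labels Binary labels (0/1).
#' @param threshold Decision threshold for the thresholded metrics.
#' @return Object of class `metrics_record`: list with `accuracy`,
#'   `precision`, `recall`, `f1`, `auroc`, `auprc`, `tp`, `fp`, `tn`, `fn`,
#'   `n`.
#' @export
compute_metrics <- function(scores, labels, threshold = 0.5) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  tn <- sum(pred == 0 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  n <- length(labels)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  structure(list(accuracy = (tp + tn) / n, precision = precision,
                 recall = recall, f1 = f1,
                 auroc = auroc(scores, labels),
                 auprc = auprc(scores, labels),
                 tp = tp, fp = fp, tn = tn, fn = fn, n = n),
            class = "metrics_record")
}

#' @export
print.metrics_record <- function(x, ...) {
  cat(sprintf(paste0("<metrics_record> n=%d acc=%.3f prec=%.3f rec=%.3f ",
                     "f1=%.3f auroc=%.3f auprc=%.3f\n"),
              x$n, x$accuracy, x$precision, x$recall, x$f1, x$auroc, x$auprc))
  invisible(x)
}

#' Area under the ROC curve (Mann-Whitney)
#'
#' Rank-based computation equivalent to counting concordant
#' positive/negative score pairs with half credit for ties.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels.
#' @return AUROC in \[0, 1\], or `NA` if only one class is present.
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (step integral)
#'
#' Walks thresholds down the unique score values and accumulates
#' `(recall_k - recall_{k-1}) * precision_k`.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels.
#' @return AUPRC in \[0, 1\], or `NA` if only one class is present.
#' @export
auprc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1)
  if (n1 == 0 || all(labels == 1)) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  grp_end <- which(c(diff(s) != 0, TRUE))
  ctp <- cumsum(y)[grp_end]
  cfp <- cumsum(1 - y)[grp_end]
  prec <- ctp / (ctp + cfp)
  rec <- ctp / n1
  sum(diff(c(0, rec)) * prec)
}
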