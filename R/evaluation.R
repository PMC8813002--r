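#' Area under the ROC curve
#'
#' Equals the (weighted) probability that a randomly drawn positive outranks
#' a randomly drawn negative, with ties counted 1/2 — the trapezoidal
#' integral of the ROC curve and the Mann-Whitney statistic. Weights, when
#' given, weight respondents within each class.
#'
#' @param y binary outcome vector (0/1); both classes must be present.
#' @param p score or probability vector (any strictly monotone transform of
#'   a score gives the same AUC).
#' @param w optional positive weights.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(y, p, w = NULL) {
  y <- as.integer(y)
  stopifnot(length(y) == length(p))
  if (is.null(w)) w <- rep(1, length(y))
  if (all(y == y[1])) stop("AUC undefined: only one class present")
  ord <- order(p)
  y <- y[ord]; p <- p[ord]; w <- w[ord]
  grp <- cumsum(!duplicated(p))  # tie groups in ascending score order
  pos_g <- tapply(w * (y == 1), grp, sum)
  neg_g <- tapply(w * (y == 0), grp, sum)
  cum_neg_before <- c(0, cumsum(neg_g))[seq_along(neg_g)]
  num <- sum(pos_g * (cum_neg_before + neg_g / 2))
  num / (sum(w[y == 1]) * sum(w[y == 0]))
}

#' Balanced error rate at a probability threshold
#'
#' `BER = 1 - (sensitivity + specificity) / 2`, the complement of balanced
#' accuracy, with class-wise (optionally weighted) rates at the given
#' threshold. Appropriate for rare outcomes, where raw error rate rewards
#' the all-negative classifier; that classifier scores BER = 0.5 here.
#' Predictions at or above the threshold count as positive.
#'
#' @param y binary outcome vector (0/1); both classes must be present.
#' @param p probability vector.
#' @param threshold probability cut-off in (0, 1).
#' @param w optional positive weights.
#' @return BER in \[0, 1\]; 0 for a perfect classifier.
#' @export
balanced_error_rate <- function(y, p, threshold = 0.5, w = NULL) {
  y <- as.integer(y)
  stopifnot(length(y) == length(p), threshold > 0, threshold < 1)
  if (is.null(w)) w <- rep(1, length(y))
  if (all(y == y[1])) stop("BER undefined: only one class present")
  pred <- as.integer(p >= threshold)
  sens <- sum(w * (y == 1 & pred == 1)) / sum(w * (y == 1))
  spec <- sum(w * (y == 0 & pred == 0)) / sum(w * (y == 0))
  1 - (sens + spec) / 2
}

#' Held-out classification metrics for a fitted model
#'
#' AUC and BER of a `penalized_fit` on a test set. Two thresholds are
#' reported: the conventional 0.5 and the prevalence-matched threshold
#' (weighted training-free: the test outcome rate), which is the informative
#' one for rare outcomes where 0.5 is degenerate.
#'
#' @param fit a `penalized_fit`.
#' @param ds an [encoded_dataset()]; the held-out test data.
#' @param threshold probability cut-off for the primary BER.
#' @param weighted use the dataset's sampling weights in the metrics?
#' @return An object of class `classification_metrics`: `auc`, `ber`,
#'   `ber_prevalence` (at the prevalence-matched threshold), `threshold`,
#'   `weighted`, `n`.
#' @export
classification_metrics <- function(fit, ds, threshold = 0.5,
                                   weighted = FALSE) {
  stopifnot(inherits(ds, "encoded_dataset"))
  p <- predict_prob(fit, ds$X)
  w <- if (weighted) ds$w else NULL
  prev <- if (weighted) stats::weighted.mean(ds$y, ds$w) else mean(ds$y)
  prev <- min(max(prev, 1e-9), 1 - 1e-9)
  structure(list(
    auc = roc_auc(ds$y, p, w),
    ber = balanced_error_rate(ds$y, p, threshold, w),
    ber_prevalence = balanced_error_rate(ds$y, p, prev, w),
    threshold = threshold, weighted = weighted, n = length(ds$y)
  ), class = "classification_metrics")
}

#' @export
print.classification_metrics <- function(x, ...) {
  cat(sprintf("<metrics> AUC %.3f, BER %.3f (at %.3g), BER %.3f (prevalence threshold), n = %d%s\n",
              x$auc, x$ber, x$threshold, x$ber_prevalence, x$n,
              if (x$weighted) ", weighted" else ""))
  invisible(x)
}

#' ROC curve points
#'
#' False- and true-positive rates over all score thresholds, for plotting or
#' CSV export.
#'
#' @inheritParams roc_auc
#' @return data.frame with columns `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(y, p, w = NULL) {
  y <- as.integer(y)
  if (is.null(w)) w <- rep(1, length(y))
  ord <- order(p, decreasing = TRUE)
  y <- y[ord]; p <- p[ord]; w <- w[ord]
  tp <- cumsum(w * (y == 1)); fp <- cumsum(w * (y == 0))
  keep <- !duplicated(p, fromLast = TRUE)
  data.frame(threshold = p[keep],
             fpr = fp[keep] / sum(w * (y == 0)),
             tpr = tp[keep] / sum(w * (y == 1)))
}
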