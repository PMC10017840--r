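#' Root mean square error
#'
#' \eqn{\mathrm{RMSE} = \sqrt{\frac{1}{n}\sum_i (\hat y_i - y_i)^2}}.
#'
#' @param predicted,actual Numeric vectors of equal, positive length.
#' @return Non-negative scalar.
#' @export
rmse <- function(predicted, actual) {
  .check_pair(predicted, actual)
  sqrt(mean((predicted - actual)^2))
}

#' Mean absolute error
#'
#' \eqn{\mathrm{MAE} = \frac{1}{n}\sum_i |\hat y_i - y_i|}.
#'
#' @inheritParams rmse
#' @return Non-negative scalar.
#' @export
mae <- function(predicted, actual) {
  .check_pair(predicted, actual)
  mean(abs(predicted - actual))
}

.check_pair <- function(predicted, actual) {
  if (!length(predicted)) stop("empty input")
  if (length(predicted) != length(actual))
    stop("'predicted' and 'actual' must have the same length")
  if (any(!is.finite(predicted)) || any(!is.finite(actual)))
    stop("inputs must be finite")
  invisible(TRUE)
}

#' ROC curve and AUC
#'
#' Sweeps every score threshold, computing the false positive rate
#' (abscissa) and true positive rate (ordinate), and integrates the curve by
#' the trapezoidal rule. Tied scores are grouped at a single threshold, so
#' the AUC equals the Mann–Whitney probability with ties counted 0.5.
#'
#' @param scores Numeric classifier scores (higher = more positive).
#' @param labels Binary labels (0/1 or logical); both classes must be
#'   present.
#' @return List with `fpr`, `tpr` (curves including the (0,0) and (1,1)
#'   endpoints) and `auc`.
#' @examples
#' roc_auc(c(0.9, 0.8, 0.3, 0.2), c(1, 0, 1, 0))$auc   # 0.75
#' @export
roc_auc <- function(scores, labels) {
  if (is.logical(labels)) labels <- as.integer(labels)
  if (!all(labels %in% c(0, 1))) stop("'labels' must be binary 0/1")
  if (length(scores) != length(labels))
    stop("'scores' and 'labels' must have the same length")
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0)
    stop("both classes must be present to compute an ROC curve")

  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  # group tied scores at one threshold
  last_of_group <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(y)[last_of_group]
  fp <- cumsum(1 - y)[last_of_group]
  tpr <- c(0, tp / n_pos)
  fpr <- c(0, fp / n_neg)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  list(fpr = fpr, tpr = tpr, auc = auc)
}
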