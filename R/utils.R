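#' Area under the receiver operating characteristic curve
#'
#' Computed from the Mann-Whitney rank statistic. Midranks for tied scores make
#' the result identical to trapezoidal integration of the empirical ROC curve.
#'
#' @param scores Numeric prediction scores (higher = more likely positive).
#' @param labels Logical (or 0/1) vector marking positives.
#' @return AUROC in `[0, 1]`, or `NA` if either class is empty.
#' @examples
#' auroc(c(0.9, 0.8, 0.7, 0.6), c(TRUE, TRUE, FALSE, TRUE))
#' @export
auroc <- function(scores, labels) {
  y <- as.logical(labels)
  stopifnot(length(scores) == length(y))
  ok <- !is.na(scores) & !is.na(y)
  scores <- scores[ok]
  y <- y[ok]
  np <- sum(y)
  nn <- sum(!y)
  if (np == 0L || nn == 0L) {
    return(NA_real_)
  }
  r <- rank(scores)
  (sum(r[y]) - np * (np + 1) / 2) / (np * nn)
}

#' Area under the precision-recall curve
#'
#' Average-precision formulation: the sum over distinct score thresholds of
#' precision times the recall increment. Tied scores are collapsed to a single
#' threshold before summation.
#'
#' @inheritParams auroc
#' @return AUPR in `(0, 1]`, or `NA` if there are no positives or no negatives.
#' @export
aupr <- function(scores, labels) {
  y <- as.logical(labels)
  stopifnot(length(scores) == length(y))
  ok <- !is.na(scores) & !is.na(y)
  scores <- scores[ok]
  y <- y[ok]
  np <- sum(y)
  if (np == 0L || sum(!y) == 0L) {
    return(NA_real_)
  }
  o <- order(scores, decreasing = TRUE)
  ys <- y[o]
  ss <- scores[o]
  tp <- cumsum(ys)
  fp <- cumsum(!ys)
  keep <- !duplicated(ss, fromLast = TRUE) # last entry of each tied block
  tp <- tp[keep]
  fp <- fp[keep]
  prec <- tp / (tp + fp)
  rec <- tp / np
  sum(diff(c(0, rec)) * prec)
}

# clip probabilities away from 0/1 so log-odds stay finite
clip_prob <- function(p, eps = 1e-6) pmin(pmax(p, eps), 1 - eps)

logit <- function(p) log(p / (1 - p))

`%||%` <- function(a, b) if (is.null(a)) b else a

# sample() without its scalar-x surprise
sample_safe <- function(x, size = length(x), replace = FALSE) {
  x[sample.int(length(x), size = size, replace = replace)]
}
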