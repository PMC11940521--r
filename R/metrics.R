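# Evaluation metrics: mean squared error and the concordance index used
# throughout the drug-target affinity literature.

#' Mean squared error
#'
#' `(1/n) * sum((actual - predicted)^2)`.
#'
#' @param actual,predicted Numeric vectors of equal positive length.
#' @return A single non-negative number.
#' @examples
#' mse(c(0, 2), c(1, 1))  # 1
#' @export
mse <- function(actual, predicted) {
  if (length(actual) != length(predicted)) {
    stop("contract error: vectors must have equal length")
  }
  if (length(actual) == 0L) stop("contract error: empty input")
  mean((actual - predicted)^2)
}

#' Concordance index for affinity ranking
#'
#' Over all pairs `(i, j)` with distinct actual values, a pair scores 1 when
#' the predictions order the pair the same way as the actual values, 0.5 when
#' the predictions are tied, and 0 otherwise; the index is the score sum
#' divided by the number of evaluable pairs. Pairs tied in the actual values
#' are excluded from the denominator. 0.5 is chance level, 1 is a perfect
#' ranking.
#'
#' @param actual,predicted Numeric vectors of equal length (at least 2).
#' @return A number in `[0, 1]`, with attribute `usable_pairs` (the
#'   denominator).
#' @examples
#' concordance_index(c(1, 2, 3), c(1, 1, 3))  # 5/6
#' @export
concordance_index <- function(actual, predicted) {
  if (length(actual) != length(predicted)) {
    stop("contract error: vectors must have equal length")
  }
  n <- length(actual)
  if (n < 2L) stop("contract error: at least two instances are required")
  dy <- outer(actual, actual, "-")
  dp <- outer(predicted, predicted, "-")
  upper <- upper.tri(dy)
  ev <- upper & dy != 0
  n_ev <- sum(ev)
  if (n_ev == 0L) {
    stop("undefined concordance index: all actual values are identical")
  }
  agree <- sign(dp[ev]) == sign(dy[ev])
  tied <- dp[ev] == 0
  ci <- (sum(agree & !tied) + 0.5 * sum(tied)) / n_ev
  structure(ci, usable_pairs = n_ev)
}
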