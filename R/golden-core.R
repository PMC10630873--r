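#' The golden ratio
#'
#' Base of the golden logarithm: phi = (1 + sqrt(5)) / 2.
#'
#' @return the golden ratio as a double.
#' @export
goldenRatio <- function() .phi

.check_lab <- function(x, what, indicator = NULL) {
  bad <- !is.finite(x) | x <= 0
  if (any(bad)) {
    where <- if (is.null(indicator)) "" else paste0(" for indicator '",
      paste(unique(indicator[bad]), collapse = "', '"), "'")
    stop(sprintf("'%s' must be positive and finite%s (got %s)",
                 what, where,
                 paste(utils::head(format(x[bad]), 3), collapse = ", ")),
         call. = FALSE)
  }
  invisible(x)
}

#' Golden logarithm of a paired measurement
#'
#' The unit of ratio response: the logarithm, to base phi, of the max/min
#' ratio of the pre- and post-treatment values. Symmetric in its arguments
#' and invariant under common rescaling (hence unit-free).
#'
#' @param pre,post positive laboratory values (vectorized).
#' @param indicator optional indicator name(s), used in error messages.
#'
#' @return non-negative numeric, `log(pmax(pre, post) / pmin(pre, post)) /
#'   log(goldenRatio())`.
#' @examples
#' goldenLog(100, 50)           # 1.4404
#' goldenLog(50, 100)           # symmetric
#' goldenLog(689.29, 50.58)     # 5.428
#' @export
goldenLog <- function(pre, post, indicator = NULL) {
  .check_lab(pre, "pre", indicator)
  .check_lab(post, "post", indicator)
  log(pmax(pre, post) / pmin(pre, post)) / log(.phi)
}

#' Direction of change (A value)
#'
#' +1 if the indicator decreased after treatment, -1 if it increased, 0 on
#' an exact tie (the tie contributes nothing to the composite score).
#'
#' @inheritParams goldenLog
#' @return integer vector in \{-1, 0, +1\}.
#' @examples
#' directionScore(10, 5)   # +1, decreased
#' directionScore(5, 10)   # -1, increased
#' @export
directionScore <- function(pre, post, indicator = NULL) {
  .check_lab(pre, "pre", indicator)
  .check_lab(post, "post", indicator)
  as.integer(sign(pre - post))
}

#' Bucketed magnitude of change (B value)
#'
#' Buckets a golden logarithm against a threshold scheme. Boundaries are
#' lower-inclusive: with the default molecular scheme, Ltau <= 0.80 -> 0,
#' 0.80 < Ltau <= 1.22 -> 1, 1.22 < Ltau <= 1.69 -> 2, Ltau > 1.69 -> 3.
#' Two-cut schemes return values in \{0, 1, 2\}.
#'
#' @param l_tau non-negative golden logarithm value(s).
#' @param scheme a [ThresholdScheme-class]; default the molecular
#'   three-cut scheme.
#'
#' @return integer vector of bucket indices, non-decreasing in `l_tau`.
#' @examples
#' magnitudeScore(0.80)  # 0 (boundary inclusive)
#' magnitudeScore(1.0)   # 1
#' magnitudeScore(2.0)   # 3
#' @export
magnitudeScore <- function(l_tau, scheme = thresholdScheme("molecular_beta")) {
  stopifnot(is(scheme, "ThresholdScheme"))
  if (any(!is.finite(l_tau)) || any(l_tau < 0))
    stop("'l_tau' must be non-negative and finite", call. = FALSE)
  as.integer(rowSums(outer(l_tau, scheme@cuts, ">")))
}
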