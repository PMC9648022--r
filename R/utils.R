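#' @importFrom stats cor pbinom phyper pnorm pt qnorm rbinom rexp rnorm runif
#'   sd setNames var kruskal.test wilcox.test p.adjust prcomp binom.test
#'   coef vcov quantile median
#' @importFrom utils combn head
NULL

#' Package log message
#'
#' Lightweight logging used by every pipeline stage to report input
#' dimensions, filter counts and the seed in effect.  Silenced by setting
#' `options(cervstage.verbose = FALSE)`.
#'
#' @param ... passed to [sprintf()].
#' @return invisibly, the formatted message.
#' @keywords internal
cs_log <- function(...) {
  msg <- sprintf(...)
  if (isTRUE(getOption("cervstage.verbose", TRUE))) message("[cervstage] ", msg)
  invisible(msg)
}

#' Round half away from zero
#'
#' Decimal rounding with ties going up (`0.05 -> 0.1`), the convention used
#' when matching printed percentage tables; base `round()` rounds half to
#' even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}
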