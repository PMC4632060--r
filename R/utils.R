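#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; published percentages in the opa
#' genotyping literature round half away from zero (10.5 -> 11, 4.75 -> 4.8).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  # the tiny epsilon absorbs binary representation error in values such as
  # 4.75 that arrive as 4.74999...
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Format a fraction as a one-decimal percent
#'
#' @param x fraction in \[0, 1\].
#' @return numeric percent rounded to one decimal, half away from zero.
#' @export
percent1 <- function(x) {
  round_half_away(100 * x, 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_notchopa <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "notchopa_error")))
}
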