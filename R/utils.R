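#' Round half-up
#'
#' Arithmetic rounding where halves go up (towards +Inf): 6.5 -> 7,
#' 7.5 -> 8. Used for all display rounding so that reported values match
#' conventional lab reporting (base R's `round()` rounds halves to even).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

stop_wheelcap <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "wheelcap_error")))
}
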