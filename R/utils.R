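#' Round half away from zero
#'
#' Reporting helper matching the convention of printed clinical tables,
#' where x.5 always rounds up (base \code{round()} rounds half to even).
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return rounded numeric vector.
#' @keywords internal
roundHalfUp <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Percentage with reporting rounding
#' @param num numerator count.
#' @param den denominator count (> 0).
#' @param digits decimals retained for reporting.
#' @keywords internal
pct <- function(num, den, digits = 0) {
  if (den <= 0) stop("undefined rate: zero denominator", call. = FALSE)
  roundHalfUp(100 * num / den, digits)
}

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

# deterministic seed derivation for sub-streams, kept within 32-bit range
deriveSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% .Machine$integer.max)
}
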