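# Shared numeric helpers.

#' Round half away from zero
#'
#' Forensic reports print thresholds, coverage and rates rounded half-up
#' (5 always rounds away from zero), unlike [base::round()] which rounds
#' half to even. All percentages and derived thresholds in this package go
#' through this helper so printed values match conventional reporting.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 0).
#' @return `x` rounded half-up to `digits` decimals.
#' @examples
#' round_half_up(0.5)      # 1, not 0
#' round_half_up(2.25, 1)  # 2.3
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# stop() with sprintf-style formatting, no call in message
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Phred qualities from an ASCII string (offset 33)
qual_to_phred <- function(qual) {
  as.integer(charToRaw(qual)) - 33L
}

phred_to_qual <- function(q) {
  rawToChar(as.raw(pmin(pmax(q, 0L), 93L) + 33L))
}
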