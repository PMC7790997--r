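#' Relative standard deviation
#'
#' RSD = sample SD / mean x 100, with the (n - 1) denominator in the SD.
#' The precision metric used by every variability gate in the workflow.
#'
#' @param x Numeric vector of measurements.
#' @return RSD in percent. `NA` if fewer than 2 values or the mean is 0.
#' @export
rsd <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) return(NA_real_)
  m <- mean(x)
  if (m == 0) return(NA_real_)
  100 * sd(x) / m
}

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; reported ratio tables use the
#' conventional half-away-from-zero rule (e.g. 3.45 -> 3.5 at one decimal).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Percent formatting used in summary tables: whole percent, half up.
format_percent <- function(frac) round_half_up(100 * frac, 0)

#' Signif-style rounding used for reported concentrations
#'
#' Reported medians and maxima follow a three-significant-figure
#' convention; full precision is kept internally.
#'
#' @param x Numeric vector.
#' @param digits Significant digits (default 3).
#' @return Rounded numeric vector.
#' @export
report_signif <- function(x, digits = 3) signif(x, digits)

stopifnot_scalar_number <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("`%s` must be a single non-missing number", name), call. = FALSE)
  }
  if (x < min) stop(sprintf("`%s` must be >= %s", name, min), call. = FALSE)
  invisible(x)
}
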