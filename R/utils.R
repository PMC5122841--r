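#' Round half away from zero
#'
#' Decimal rounding where ties (x.5 at the last kept digit) round up in
#' magnitude, as in most spreadsheet software and printed ecology tables.
#' `base::round` rounds half to even, which differs on exactly those ties.
#'
#' @param x numeric vector.
#' @param digits number of decimal places to keep.
#' @return numeric vector rounded half-up.
#' @export
#' @examples
#' round_half_up(2.675, 2)  # 2.68, where round() gives 2.67
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Percentage of a count, rounded half-up to two decimals
#'
#' @param count numerator count.
#' @param total denominator count; must be positive.
#' @return numeric percentage on the 0-100 scale.
#' @export
#' @examples
#' pct_half_up(63060, 173769)  # 36.29
pct_half_up <- function(count, total) {
  stopifnot(is.numeric(count), is.numeric(total), all(total > 0))
  round_half_up(100 * count / total, 2)
}

#' Format a count as "X% (n out of N)"
#'
#' The reporting convention used for habitat-classification summaries.
#'
#' @inheritParams pct_half_up
#' @return character vector.
#' @export
#' @examples
#' format_percent(1322, 173769)  # "0.76% (1322 out of 173769)"
format_percent <- function(count, total) {
  sprintf("%.2f%% (%s out of %s)", pct_half_up(count, total),
          format(count, scientific = FALSE, trim = TRUE),
          format(total, scientific = FALSE, trim = TRUE))
}

# Derive a reproducible sub-seed (< 2^31) from a base seed and a stage tag.
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
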