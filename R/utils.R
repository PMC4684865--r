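#' Round half away from zero
#'
#' Decimal rounding in which a value exactly halfway between two neighbours
#' is rounded up (2.45 -> 2.5), the convention used for all reported synergy
#' ratios. This differs from [base::round()], which rounds half to even.
#'
#' @param x Numeric vector (non-negative in all package uses).
#' @param digits Number of decimal places to keep.
#' @return Numeric vector rounded half-up to `digits` decimals.
#' @examples
#' round_half_up(c(7.553, 3.879, 1.95), 1)
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  # small epsilon guards values whose binary representation sits a hair
  # below the .5 boundary (e.g. 1.75 stored as 1.74999...)
  floor(x * p + 0.5 + 1e-9) / p
}

# Stable 31-bit polynomial fingerprint of a string; used to stamp run
# reports with a config fingerprint that is identical across platforms.
string_fingerprint <- function(s) {
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == trunc(x)
}

is_prop <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
}
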