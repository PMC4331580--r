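#' Round half away from zero
#'
#' Commercial ("table-style") rounding: ties go away from zero, so 4.65
#' reported at one decimal is 4.7 and -4.65 is -4.7.  R's [round()] uses
#' banker's rounding and cannot reproduce printed summary tables.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (may be negative or vectorised).
#' @return Numeric vector rounded half away from zero.
#' @examples
#' round_away(c(0.5, 1.5, 2.5))   # 1 2 3
#' round_away(26.33)              # 26
#' @export
round_away <- function(x, digits = 0) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' Round to significant figures, half away from zero
#'
#' Significant-figure analogue of [round_away()], used for reported
#' electron quantities and percentages (two significant figures by table
#' convention, e.g. 73.96 -> 74 and 4.615 -> 4.6).
#'
#' @param x Numeric vector.
#' @param digits Significant figures to keep.
#' @return Numeric vector.
#' @examples
#' signif_away(c(73.958, 4.615, 30.93), 2)  # 74 4.6 31
#' @export
signif_away <- function(x, digits = 2) {
  out <- x
  nz <- !is.na(x) & x != 0 & is.finite(x)
  if (any(nz)) {
    m <- floor(log10(abs(x[nz])))
    out[nz] <- round_away(x[nz], digits - 1 - m)
  }
  out
}
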