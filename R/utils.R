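#' Round half away from zero
#'
#' Presentation rounding used in reports: 25.45 -> 25.5, -25.45 -> -25.5.
#' R's [round()] rounds half to even, which does not match how trait tables
#' in the plant-breeding literature are printed.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
stop_ <- function(..., call. = FALSE) stop(..., call. = call.)

# Significance stars at the conventional 0.05 / 0.01 / 0.001 cutoffs.
#' @noRd
sig_stars <- function(p) {
  ifelse(is.na(p), "", ifelse(p <= 0.001, "***",
    ifelse(p <= 0.01, "**", ifelse(p <= 0.05, "*", "ns"))))
}
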