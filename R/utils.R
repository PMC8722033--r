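#' Round half away from zero
#'
#' Fixed-point rounding with halves going up (away from zero for positive
#' input), matching how diagnostic rates are conventionally printed.
#' `base::round()` rounds halves to even, which would turn 35.005 into 35.00.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# internal: stopifnot-style check with a formatted message
.check <- function(cond, ..., call. = FALSE) {
  if (!isTRUE(cond)) stop(sprintf(...), call. = call.)
}

# internal: deterministic order of chromosome names (as given in a model)
.chrom_order <- function(chroms, levels) {
  match(as.character(chroms), levels)
}
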