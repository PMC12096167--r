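#' Round half away from zero
#'
#' Commercial ("round half up") rounding to the nearest integer, as opposed to
#' the IEC 60559 banker's rounding of [base::round()]. Used wherever the model
#' reports whole children or whole formula cans: 12,333.77 children round to
#' 12,334 and 5.58 cans to 6.
#'
#' @param x numeric vector.
#' @return `x` rounded to the nearest integer, ties away from zero.
#' @examples
#' round_half_up(c(0.5, 1.5, 2.49, -0.5))
#' @export
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# stop() with a call-free, single-string message
fail <- function(...) stop(paste0(...), call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == trunc(x)
}

is_prob <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
}

is_pos <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0
}
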