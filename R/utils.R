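#' Round half up
#'
#' Rounds to `digits` decimal places with ties going away from zero, the
#' convention used for printed module completion ratios (85.714... -> 85.7).
#' Base `round()` uses banker's rounding, which would print 82.25 as 82.2.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up.
#' @export
#' @examples
#' round_half_up(100 * 6 / 7, 1) # 85.7
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

## internal: stop() with a consistent condition class so callers/tests can
## distinguish validation failures from programming errors
mc_stop <- function(..., class = "modcomp_error", call. = FALSE) {
  stop(errorCondition(paste0(...), class = c(class, "error", "condition")))
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

`%||%` <- function(a, b) if (is.null(a)) b else a
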