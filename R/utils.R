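#' Round half away from zero
#'
#' Rounds to `digits` decimal places with exact halves rounded away from
#' zero (the convention used when reporting percentages in tables), unlike
#' [base::round()] which rounds halves to even.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector of the same length as `x`.
#' @examples
#' round_half_up(2.5)      # 3
#' round_half_up(35.725, 2)
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# stop() with a consistent prefix so callers can match on it
.fail <- function(...) stop(sprintf(...), call. = FALSE)

.is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x == floor(x)

#' @keywords internal
"_PACKAGE"
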