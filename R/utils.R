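#' Round half-up
#'
#' Rounds to `digits` decimal places with ties going away from zero, the
#' convention under which every published percentage in the packaged count
#' fixtures reproduces exactly from its integer counts (e.g. 629/738 ->
#' 85.2). Base [round()] rounds half-to-even and would disagree on ties.
#'
#' @param x numeric vector.
#' @param digits decimal places (default 1).
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_up(0.25, 1)  # 0.3, where round(0.25, 1) gives 0.2
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Percentage with half-up rounding to one decimal
#'
#' @param num integer numerator.
#' @param den integer denominator.
#' @return percentage on the 0-100 scale, one decimal, or `NA` when the
#'   denominator is zero.
#' @export
pct1 <- function(num, den) {
  ifelse(den > 0, round_half_up(100 * num / den, 1), NA_real_)
}

# A rate always travels with its integer numerator and denominator so that
# no percentage in any output is rounded independently of its counts.
rate_record <- function(num, den) {
  stopifnot(length(num) == 1, length(den) == 1)
  list(
    numerator = as.integer(num),
    denominator = as.integer(den),
    proportion = if (den > 0) num / den else NA_real_,
    percent = pct1(num, den)
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x
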