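# Shared helpers. Percent rounding is half-up (not banker's) because the
# published tables the audit mode reproduces were rounded that way.

round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percentage of a count over a total, rounded half-up
#'
#' Small arithmetic helper used by every summary in the package: computes
#' `100 * n / total` and rounds half-up to `digits` decimals, matching the way
#' percentages are conventionally printed in ChIP-seq summary tables.
#'
#' @param n Numerator count(s).
#' @param total Denominator count(s); must be positive.
#' @param digits Decimal places to keep (default 1).
#' @return A numeric vector of percentages.
#' @export
#' @examples
#' percent_of(519, 12280) # 4.2
percent_of <- function(n, total, digits = 1) {
  if (any(total <= 0)) {
    abort("percentage undefined: total must be positive",
          class = "enrichdiff_undefined_percentage")
  }
  round_half_up(100 * n / total, digits)
}

# Derived random streams: one global seed, fixed offsets per component, so
# adding a generator never perturbs the draws of an earlier one.
stream_offsets <- c(
  genome = 101L, landscape = 202L, coverage_wt = 303L, coverage_ko = 404L,
  expression = 505L, background = 606L
)

with_stream <- function(seed, component, code) {
  offset <- stream_offsets[[component]]
  withr::with_seed(as.integer(seed) + offset, code)
}

assert_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf("%s is missing column(s): %s", what,
                  paste(missing, collapse = ", ")),
          class = "enrichdiff_bad_input")
  }
  invisible(df)
}

# Distance from an interval [start, end) to a point; 0 when the point is inside.
interval_point_distance <- function(start, end, point) {
  pmax(0, start - point, point - (end - 1L))
}

# Distance in bp between half-open intervals, consistent with
# interval_point_distance (adjacent base pairs are 1 bp apart; 0 = overlap).
interval_distance <- function(s1, e1, s2, e2) {
  pmax(0, s1 - e2 + 1, s2 - e1 + 1)
}
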