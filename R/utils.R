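`%||%` <- function(x, y) if (is.null(x)) y else x

#' Round half-up to a given unit
#'
#' Rounds `x` to the nearest multiple of `unit`, with exact halves rounded
#' away from zero-adjacent ties towards the larger multiple ("half-up").
#' Base R's `round()` rounds halves to even, which does not reproduce the
#' conventions used when reporting dates in years.
#'
#' @param x numeric vector.
#' @param unit positive rounding unit (e.g. 100 or 1000 years).
#' @return numeric vector of rounded values.
#' @examples
#' round_half_up(49938, 100)  # 49900
#' round_half_up(59350, 100)  # 59400
#' @export
round_half_up <- function(x, unit = 1) {
  stopifnot(is.numeric(x), is.numeric(unit), unit > 0)
  floor(x / unit + 0.5) * unit
}

#' Round a time in years for reporting
#'
#' Dates below `cutoff` are rounded to the nearest `small_unit` (default 100
#' years), dates at or above it to the nearest `large_unit` (default 1000
#' years), always half-up. This is the reporting convention used throughout
#' the package for split-time point estimates and confidence bounds.
#'
#' @param x numeric vector of times in years.
#' @param small_unit,large_unit rounding units below/above the cutoff.
#' @param cutoff boundary in years between the two units.
#' @return numeric vector of rounded times.
#' @export
round_years <- function(x, small_unit = 100, large_unit = 1000, cutoff = 1e5) {
  unit <- ifelse(abs(x) < cutoff, small_unit, large_unit)
  floor(x / unit + 0.5) * unit
}

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    stop(sprintf("`%s` must be a single number in [%s, %s]", name, lower, upper),
         call. = FALSE)
  }
  invisible(x)
}
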