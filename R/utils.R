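#' Rounding conventions used in report tables
#'
#' `round_half_up()` rounds halves towards positive infinity (1.5 -> 2,
#' used when merging duplicate same-day item scores).  `round_half_away()`
#' rounds halves away from zero (-46.5 -> -47, used for integer percent
#' columns in report tables).  Base `round()` rounds halves to even, which
#' is not the convention used in clinical report tables.
#'
#' @param x numeric vector.
#' @return numeric vector of rounded values.
#' @examples
#' round_half_up(c(1.5, 2.5, -0.5))
#' round_half_away(c(46.5, -46.5))
#' @export
round_half_up <- function(x) {
  floor(x + 0.5)
}

#' @rdname round_half_up
#' @export
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Percent change from a baseline value
#'
#' Computes `100 * (new - baseline) / baseline`; negative values are
#' improvements.  Undefined (baseline 0 or missing) yields `NA`.
#'
#' @param baseline,new numeric vectors, recycled to common length.
#' @return numeric vector of percent changes.
#' @examples
#' pct_change(17.8, 9.6)
#' pct_change(0, 5) # NA: undefined when baseline is 0
#' @export
pct_change <- function(baseline, new) {
  out <- 100 * (new - baseline) / baseline
  out[!is.na(baseline) & baseline == 0] <- NA_real_
  out
}

# stop() with a classed condition so callers can distinguish endpoint
# preconditions from programming errors.
abort_endpoint_undefined <- function(msg) {
  cond <- structure(
    class = c("nutricohort_endpoint_undefined", "error", "condition"),
    list(message = msg, call = NULL)
  )
  stop(cond)
}
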