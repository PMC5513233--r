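# Classed error conditions so callers and tests can discriminate failure modes.

abort <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "carrionfate_error"), call = call))
}

abort_validation <- function(msg) abort(msg, "carrionfate_validation_error")
abort_integrity  <- function(msg) abort(msg, "carrionfate_integrity_error")
abort_ordering   <- function(msg) abort(msg, "carrionfate_ordering_error")
abort_data       <- function(msg) abort(msg, "carrionfate_insufficient_data_error")
abort_calibration <- function(msg) abort(msg, "carrionfate_calibration_error")

# Field-naming validators used by the config constructors --------------------

check_number <- function(x, field, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    abort_validation(sprintf(
      "field '%s' must be a single number in [%s, %s]; got %s",
      field, format(lower), format(upper),
      paste(format(x), collapse = ", ")))
  }
  x
}

check_count <- function(x, field, lower = 0L) {
  check_number(x, field, lower = lower)
  if (x != as.integer(x)) {
    abort_validation(sprintf("field '%s' must be an integer count", field))
  }
  as.integer(x)
}

check_range <- function(x, field, lower = 0) {
  if (!is.numeric(x) || length(x) != 2L || any(is.na(x)) ||
      x[1] > x[2] || x[1] <= lower) {
    abort_validation(sprintf(
      "field '%s' must be an increasing pair (min, max) with min > %s",
      field, format(lower)))
  }
  as.numeric(x)
}

check_fraction <- function(x, field) check_number(x, field, lower = 0, upper = 1)

`%||%` <- function(a, b) if (is.null(a)) b else a
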