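# Timestamp handling. Everything is UTC internally; ISO-8601 on disk.

parse_utc <- function(x) {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- "UTC"
    return(x)
  }
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%dT%H:%M:%OSZ", "%Y-%m-%dT%H:%M:%OS",
                                   "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d"))
  out
}

format_utc <- function(x) {
  format(x, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
}

# Decimal hour of day (UTC unless an offset in hours is supplied, e.g. +1 for
# British Summer Time display).
#' Time of day in decimal hours
#'
#' @param time POSIXct vector.
#' @param utc_offset_h Constant offset in hours applied before taking the
#'   time of day (display convenience; analysis stays in UTC).
#' @return Numeric vector in `[0, 24)`.
#' @export
time_of_day_hours <- function(time, utc_offset_h = 0) {
  secs <- as.numeric(time) + utc_offset_h * 3600
  (secs %% 86400) / 3600
}
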