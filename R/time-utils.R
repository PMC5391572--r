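# Internal time helpers. All timestamps in the package are POSIXct with an
# explicit tzone; serialization is ISO-8601 with numeric offset so round trips
# are exact to the second.

#' @keywords internal
#' @noRd
fmt_iso <- function(t) {
  format(t, "%Y-%m-%dT%H:%M:%S%z")
}

#' @keywords internal
#' @noRd
parse_iso <- function(x, tz = "UTC") {
  out <- as.POSIXct(strptime(x, "%Y-%m-%dT%H:%M:%S%z", tz = "UTC"))
  bad <- is.na(out) & !is.na(x)
  if (any(bad)) {
    # fall back to a plain local-time format
    out[bad] <- as.POSIXct(strptime(x[bad], "%Y-%m-%d %H:%M:%S", tz = tz))
  }
  attr(out, "tzone") <- tz
  out
}

# Clock time "HH:MM" -> seconds past midnight.
#' @keywords internal
#' @noRd
clock_to_seconds <- function(x) {
  parts <- strsplit(x, ":", fixed = TRUE)[[1]]
  if (length(parts) < 2L) stop("clock time must be 'HH:MM[:SS]': ", x)
  as.numeric(parts[1L]) * 3600 + as.numeric(parts[2L]) * 60 +
    if (length(parts) >= 3L) as.numeric(parts[3L]) else 0
}

# The most recent boundary-hour instant at or before `t`, in local tz.
#' @keywords internal
#' @noRd
floor_to_boundary <- function(t, boundary_hour, tz) {
  lt <- as.POSIXlt(t, tz = tz)
  day <- as.POSIXct(
    sprintf("%04d-%02d-%02d %02d:00:00",
            lt$year + 1900L, lt$mon + 1L, lt$mday, boundary_hour),
    tz = tz
  )
  if (day > t) day <- day - 86400
  day
}
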