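#' Channel metadata
#'
#' The three continuous channels and their units: pulse-oximetry oxygen
#' saturation (`spo2`, percent), heart rate (`heart_rate`, beats per minute)
#' and actigraph activity (`activity`, vector magnitude units).
#'
#' @format A named character vector mapping channel name to unit.
#' @keywords internal
CHANNEL_UNITS <- c(spo2 = "percent", heart_rate = "bpm", activity = "vmu")

#' Construct a continuous channel series
#'
#' A channel series holds the timestamped 1 Hz-class samples of one continuous
#' channel. The constructor preserves sample order as given (so that
#' [validate_record()] can report ordering problems); analysis functions sort
#' defensively. The nominal 1 Hz rate is not enforced: gaps and irregular
#' sampling are permitted and handled downstream (wear detection splits on
#' gaps).
#'
#' @param channel One of `"spo2"`, `"heart_rate"`, `"activity"`.
#' @param t `POSIXct` sample timestamps (seconds resolution).
#' @param value Numeric sample values in the channel's unit.
#' @return An object of class `channel_series` with fields `channel`, `unit`,
#'   `t`, `value`.
#' @export
channel_series <- function(channel, t, value) {
  channel <- match.arg(channel, names(CHANNEL_UNITS))
  if (!inherits(t, "POSIXct")) stop("`t` must be POSIXct")
  if (length(t) != length(value)) stop("`t` and `value` lengths differ")
  structure(
    list(channel = channel, unit = unname(CHANNEL_UNITS[channel]),
         t = t, value = as.numeric(value)),
    class = "channel_series"
  )
}

#' @export
print.channel_series <- function(x, ...) {
  cat(sprintf("<channel_series> %s [%s], %d samples\n",
              x$channel, x$unit, length(x$t)))
  invisible(x)
}

# Sorted copy of a channel series (stable by t). Duplicate timestamps are kept.
#' @keywords internal
#' @noRd
sort_series <- function(series) {
  o <- order(series$t)
  series$t <- series$t[o]
  series$value <- series$value[o]
  series
}

#' Construct an episodic measurement
#'
#' Episodic data are the once-or-few-per-day entries: body weight, a blood
#' pressure reading, or a subjective-state question set with its summary
#' score. Exactly the fields for the given kind must be supplied.
#'
#' @param kind `"weight"`, `"blood_pressure"` or `"subjective"`.
#' @param t `POSIXct` timestamp of the measurement.
#' @param weight_kg Positive weight in kilograms (kind `weight`).
#' @param systolic_mmhg,diastolic_mmhg Positive pressures with
#'   `systolic_mmhg > diastolic_mmhg` (kind `blood_pressure`).
#' @param subjective_score Summary score of the question set (kind
#'   `subjective`).
#' @param subjective_items Named numeric vector of per-category values that
#'   gave rise to the score (kind `subjective`; may be empty).
#' @return An object of class `episodic_measurement`.
#' @export
episodic_measurement <- function(kind, t, weight_kg = NULL,
                                 systolic_mmhg = NULL, diastolic_mmhg = NULL,
                                 subjective_score = NULL,
                                 subjective_items = NULL) {
  kind <- match.arg(kind, c("weight", "blood_pressure", "subjective"))
  if (!inherits(t, "POSIXct") || length(t) != 1L) {
    stop("`t` must be a single POSIXct timestamp")
  }
  m <- structure(list(kind = kind, t = t), class = "episodic_measurement")
  if (kind == "weight") {
    if (is.null(weight_kg) || weight_kg <= 0) stop("weight_kg must be > 0")
    m$weight_kg <- as.numeric(weight_kg)
  } else if (kind == "blood_pressure") {
    if (is.null(systolic_mmhg) || is.null(diastolic_mmhg)) {
      stop("blood_pressure needs systolic_mmhg and diastolic_mmhg")
    }
    if (systolic_mmhg <= 0 || diastolic_mmhg <= 0) stop("pressures must be > 0")
    if (systolic_mmhg <= diastolic_mmhg) {
      stop("systolic_mmhg must exceed diastolic_mmhg")
    }
    m$systolic_mmhg <- as.numeric(systolic_mmhg)
    m$diastolic_mmhg <- as.numeric(diastolic_mmhg)
  } else {
    if (is.null(subjective_score)) stop("subjective needs subjective_score")
    m$subjective_score <- as.numeric(subjective_score)
    items <- if (is.null(subjective_items)) numeric(0) else subjective_items
    m$subjective_items <- items
  }
  m
}

#' Threshold configuration
#'
#' The per-channel alerting thresholds used for 30-minute violation blocks:
#' oxygen saturation below 92%, heart rate below 60 or above 100 bpm, and
#' 30-minute mean activity above 12 vector magnitude units. All comparisons
#' are strict; boundary values never flag.
#'
#' @param spo2_low SpO2 lower threshold, percent.
#' @param hr_low,hr_high Heart-rate lower/upper thresholds, bpm.
#' @param activity_high Activity block-mean threshold, vector magnitude units.
#' @param block_minutes Block grid size in minutes; must divide 60.
#' @param min_violation_samples Minimum number of threshold-crossing samples
#'   needed to flag an SpO2/heart-rate block (default 1, i.e. any single
#'   sample). Does not apply to the activity mean rule.
#' @return An object of class `threshold_config`.
#' @export
threshold_config <- function(spo2_low = 92, hr_low = 60, hr_high = 100,
                             activity_high = 12, block_minutes = 30L,
                             min_violation_samples = 1L) {
  if (hr_low >= hr_high) stop("hr_low must be < hr_high")
  if (any(c(spo2_low, hr_low, hr_high, activity_high) <= 0)) {
    stop("thresholds must be positive")
  }
  block_minutes <- as.integer(block_minutes)
  if (block_minutes <= 0L || 60L %% block_minutes != 0L) {
    stop("block_minutes must divide 60")
  }
  if (min_violation_samples < 1L) stop("min_violation_samples must be >= 1")
  structure(
    list(spo2_low = spo2_low, hr_low = hr_low, hr_high = hr_high,
         activity_high = activity_high, block_minutes = block_minutes,
         min_violation_samples = as.integer(min_violation_samples)),
    class = "threshold_config"
  )
}

#' Partition timestamps into clinical days
#'
#' A clinical day runs from 4 pm local time to 4 pm the following day, so a
#' full night of monitoring lies inside one window. Day 1 starts at the most
#' recent boundary-hour instant at or before the earliest datum; windows are
#' contiguous fixed 86400-s spans and half-open `[start, end)`, so a datum at
#' exactly 16:00 belongs to the day beginning then.
#'
#' @param times `POSIXct` vector of every timestamped datum for one patient
#'   (continuous samples and episodic entries together).
#' @param day_boundary_hour Local hour at which days roll over (default 16).
#' @param tz Timezone in which the boundary hour is evaluated (default the
#'   tzone of `times`, else UTC).
#' @return A data frame with columns `index`, `start`, `end`, one row per
#'   clinical day, covering every datum.
#' @export
partition_days <- function(times, day_boundary_hour = 16L, tz = NULL) {
  if (length(times) == 0L) stop("no data: cannot partition an empty record")
  if (!inherits(times, "POSIXct")) stop("`times` must be POSIXct")
  if (anyNA(times)) stop("`times` contains missing values")
  if (is.null(tz)) tz <- attr(times, "tzone") %||% "UTC"
  if (identical(tz, "")) tz <- "UTC"
  start1 <- floor_to_boundary(min(times), day_boundary_hour, tz)
  n <- as.integer(floor(as.numeric(difftime(max(times), start1, units = "secs")) /
                          86400)) + 1L
  starts <- start1 + (seq_len(n) - 1L) * 86400
  data.frame(index = seq_len(n), start = starts, end = starts + 86400)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assemble a patient record
#'
#' Bundles the continuous channel series, episodic measurements and clinical
#' day windows for one anonymous patient. If `days` is omitted it is derived
#' from the union of all timestamps via [partition_days()].
#'
#' @param patient_id Opaque patient identifier.
#' @param display_name Name shown in the display header.
#' @param channels List of [channel_series()] objects, at most one per channel.
#' @param episodic List of [episodic_measurement()] objects.
#' @param days Optional data frame of day windows as from [partition_days()].
#' @param tz Record-local timezone used for the 16:00 day boundary.
#' @param day_boundary_hour Boundary hour when deriving `days`.
#' @return An object of class `patient_record`.
#' @export
patient_record <- function(patient_id, display_name = patient_id,
                           channels = list(), episodic = list(),
                           days = NULL, tz = "UTC", day_boundary_hour = 16L) {
  chn <- vapply(channels, function(s) s$channel, character(1))
  names(channels) <- chn
  if (anyDuplicated(chn)) stop("each channel may appear at most once")
  if (is.null(days)) {
    all_t <- record_times(channels, episodic)
    days <- partition_days(all_t, day_boundary_hour, tz)
  }
  structure(
    list(patient_id = patient_id, display_name = display_name,
         channels = channels, episodic = episodic, days = days, tz = tz),
    class = "patient_record"
  )
}

#' @export
print.patient_record <- function(x, ...) {
  cat(sprintf("<patient_record> %s (%s): %d day(s), channels: %s, %d episodic\n",
              x$patient_id, x$display_name, nrow(x$days),
              paste(names(x$channels), collapse = ", "),
              length(x$episodic)))
  invisible(x)
}

#' @keywords internal
#' @noRd
record_times <- function(channels, episodic) {
  ts <- lapply(channels, function(s) s$t)
  te <- lapply(episodic, function(m) m$t)
  all_t <- do.call(c, c(ts, te))
  if (is.null(all_t)) all_t <- as.POSIXct(character(0), tz = "UTC")
  all_t
}

#' Validate a patient record
#'
#' Checks every structural invariant of a record and returns one message per
#' violation; a well-formed record yields an empty character vector. Content
#' problems never raise errors here, so a caller can report them all at once.
#'
#' Checked: finite sample values and timestamps, strictly increasing sample
#' order (the first inversion is named), SpO2 in \[0, 100\], non-negative heart
#' rate and activity, episodic systolic > diastolic, and every timestamp
#' falling inside the union of the record's day windows.
#'
#' @param record A [patient_record()].
#' @return Character vector of violation messages (empty when valid).
#' @export
validate_record <- function(record) {
  msgs <- character(0)
  days <- record$days
  in_days <- function(t) {
    any(t >= days$start & t < days$end)
  }
  for (s in record$channels) {
    n <- length(s$t)
    if (n == 0L) next
    if (anyNA(s$t) || any(!is.finite(as.numeric(s$t)))) {
      msgs <- c(msgs, sprintf("%s: non-finite timestamp", s$channel))
    }
    if (anyNA(s$value) || any(!is.finite(s$value))) {
      msgs <- c(msgs, sprintf("%s: non-finite sample value", s$channel))
    }
    d <- diff(as.numeric(s$t))
    if (any(d <= 0, na.rm = TRUE)) {
      i <- which(d <= 0)[1L]
      msgs <- c(msgs, sprintf(
        "%s: samples not strictly increasing; first inversion at index %d (%s)",
        s$channel, i + 1L, fmt_iso(s$t[i + 1L])))
    }
    if (s$channel == "spo2") {
      bad <- which(s$value < 0 | s$value > 100)
      if (length(bad)) {
        msgs <- c(msgs, sprintf(
          "spo2: value %g at %s outside [0, 100]",
          s$value[bad[1L]], fmt_iso(s$t[bad[1L]])))
      }
    } else {
      bad <- which(s$value < 0)
      if (length(bad)) {
        msgs <- c(msgs, sprintf(
          "%s: negative value %g at %s",
          s$channel, s$value[bad[1L]], fmt_iso(s$t[bad[1L]])))
      }
    }
    outside <- !vapply(seq_len(n), function(i) in_days(s$t[i]), logical(1))
    if (any(outside)) {
      msgs <- c(msgs, sprintf(
        "%s: %d sample(s) outside the record's day windows (first at %s)",
        s$channel, sum(outside), fmt_iso(s$t[which(outside)[1L]])))
    }
  }
  for (m in record$episodic) {
    if (m$kind == "blood_pressure" && m$systolic_mmhg <= m$diastolic_mmhg) {
      msgs <- c(msgs, sprintf(
        "blood_pressure at %s: systolic (%g) not above diastolic (%g)",
        fmt_iso(m$t), m$systolic_mmhg, m$diastolic_mmhg))
    }
    if (!in_days(m$t)) {
      msgs <- c(msgs, sprintf("%s at %s outside the record's day windows",
                              m$kind, fmt_iso(m$t)))
    }
  }
  if (nrow(days) > 1L) {
    if (any(abs(diff(as.numeric(days$start)) - 86400) > 1e-6)) {
      msgs <- c(msgs, "day windows are not contiguous 24-h spans")
    }
  }
  msgs
}

#' Day window accessor
#'
#' @param record A [patient_record()].
#' @param index Clinical day number (1-based).
#' @return One-row data frame with `index`, `start`, `end`.
#' @export
day_window <- function(record, index) {
  i <- match(index, record$days$index)
  if (is.na(i)) {
    stop(sprintf("record has no day %s (days 1..%d)", index, nrow(record$days)))
  }
  record$days[i, , drop = FALSE]
}
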