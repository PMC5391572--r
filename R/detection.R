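#' The 30-minute block grid of a clinical day
#'
#' Contiguous half-open intervals anchored at the day start (16:00 local), the
#' same grid used for sleep-slot detection, violation blocks and the Layer-2
#' display. Anchoring at the day start rather than at sleep onset keeps block
#' boundaries stable and comparable across days.
#'
#' @param day One-row day-window data frame (`start`, `end`).
#' @param block_minutes Block size in minutes; must divide 1440.
#' @return Data frame with `start`, `end`, one row per grid interval
#'   (48 rows for 30-minute blocks).
#' @export
block_grid <- function(day, block_minutes = 30L) {
  if (1440L %% as.integer(block_minutes) != 0L) {
    stop("block_minutes must divide 1440")
  }
  n <- 1440L %/% as.integer(block_minutes)
  starts <- day$start + (seq_len(n) - 1L) * block_minutes * 60
  data.frame(start = starts, end = starts + block_minutes * 60)
}

# Samples of one channel falling in [day$start, day$end); sorted by t.
#' @keywords internal
#' @noRd
day_samples <- function(record, channel, day) {
  s <- record$channels[[channel]]
  if (is.null(s) || length(s$t) == 0L) {
    return(data.frame(t = as.POSIXct(character(0), tz = record$tz),
                      value = numeric(0)))
  }
  s <- sort_series(s)
  keep <- s$t >= day$start & s$t < day$end
  data.frame(t = s$t[keep], value = s$value[keep])
}

#' Detect the sleeping period of a clinical day
#'
#' The sleeping period spans from the first to the last time slot of the day
#' that contains any oxygen-saturation or heart-rate sample: the pulse
#' oximeter is worn only in bed, so the presence of either channel marks the
#' monitored night. Slots are `slot_minutes`-wide intervals anchored at the
#' day start.
#'
#' @param record A [patient_record()].
#' @param day One-row day window belonging to the record.
#' @param slot_minutes Slot width in minutes (default 30, the block grid).
#' @return A list with `day_index`, `start`, `end`, or `NULL` when neither
#'   channel has samples in the day (a valid outcome, not an error).
#' @export
detect_sleep_period <- function(record, day, slot_minutes = 30L) {
  t <- c(day_samples(record, "spo2", day)$t,
         day_samples(record, "heart_rate", day)$t)
  if (length(t) == 0L) return(NULL)
  slot <- floor(as.numeric(difftime(t, day$start, units = "secs")) /
                  (slot_minutes * 60))
  first <- min(slot); last <- max(slot)
  list(day_index = day$index,
       start = day$start + first * slot_minutes * 60,
       end = day$start + (last + 1) * slot_minutes * 60)
}

#' Detect pulse-oximeter wear intervals
#'
#' Wear is the set of maximal intervals over which the SpO2 channel keeps
#' producing data: consecutive samples at most `gap_tolerance` seconds apart
#' belong to the same interval. Rendered as the blue line of Layer 1; no SpO2
#' samples means no wear (the line is absent).
#'
#' @param record A [patient_record()].
#' @param day One-row day window.
#' @param gap_tolerance Maximum inter-sample gap, seconds (default 60).
#' @return List with `day_index` and `intervals`, a data frame of disjoint
#'   sorted `start`/`end` pairs (zero rows when the oximeter was not worn).
#' @export
detect_wear <- function(record, day, gap_tolerance = 60) {
  t <- day_samples(record, "spo2", day)$t
  if (length(t) == 0L) {
    iv <- data.frame(start = as.POSIXct(character(0), tz = record$tz),
                     end = as.POSIXct(character(0), tz = record$tz))
    return(list(day_index = day$index, intervals = iv))
  }
  brk <- which(diff(as.numeric(t)) > gap_tolerance)
  starts <- t[c(1L, brk + 1L)]
  ends <- t[c(brk, length(t))]
  list(day_index = day$index, intervals = data.frame(start = starts, end = ends))
}

# Per-block summaries of time-sorted samples: `idx` is the non-decreasing
# block index of each sample. Much faster than tapply (no factor built).
#' @keywords internal
#' @noRd
block_stats <- function(idx, v) {
  r <- rle(idx)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(
    block = r$values,
    n = r$lengths,
    mean = vapply(seq_along(ends), function(i) mean(v[starts[i]:ends[i]]),
                  numeric(1)),
    min = vapply(seq_along(ends), function(i) min(v[starts[i]:ends[i]]),
                 numeric(1)),
    max = vapply(seq_along(ends), function(i) max(v[starts[i]:ends[i]]),
                 numeric(1))
  )
}

#' @keywords internal
#' @noRd
block_count_if <- function(idx, hit) {
  r <- rle(idx)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  vapply(seq_along(ends), function(i) sum(hit[starts[i]:ends[i]]), numeric(1))
}

#' @keywords internal
#' @noRd
empty_blocks <- function(tz) {
  data.frame(channel = character(0), kind = character(0),
             start = as.POSIXct(character(0), tz = tz),
             end = as.POSIXct(character(0), tz = tz),
             statistic = numeric(0), n_samples = integer(0))
}

#' Flag activity violation blocks
#'
#' A grid interval of the activity channel is flagged when its sample mean is
#' strictly above the activity threshold (block mean above 12 vector
#' magnitude units is considered real activity). The flagged statistic is
#' that mean. Blocks with no samples are absent, never flagged.
#'
#' @param series Activity [channel_series()].
#' @param day One-row day window.
#' @param cfg A [threshold_config()].
#' @return Data frame of violation blocks (`channel`, `kind`, `start`, `end`,
#'   `statistic`, `n_samples`).
#' @export
flag_activity_blocks <- function(series, day, cfg = threshold_config()) {
  if (series$channel != "activity") stop("series must be the activity channel")
  s <- sort_series(series)
  keep <- s$t >= day$start & s$t < day$end
  t <- s$t[keep]; v <- s$value[keep]
  if (length(t) == 0L) return(empty_blocks(attr(day$start, "tzone")))
  bw <- cfg$block_minutes * 60
  idx <- floor((as.numeric(t) - as.numeric(day$start)) / bw)
  st <- block_stats(idx, v)
  st <- st[st$mean > cfg$activity_high, , drop = FALSE]
  if (nrow(st) == 0L) return(empty_blocks(attr(day$start, "tzone")))
  data.frame(channel = "activity", kind = "high",
             start = day$start + st$block * bw,
             end = day$start + (st$block + 1) * bw,
             statistic = st$mean, n_samples = as.integer(st$n))
}

#' Flag SpO2 / heart-rate violation blocks
#'
#' A grid interval is flagged `low` when at least `min_violation_samples`
#' samples fall strictly below the lower threshold (SpO2 below 92%, heart
#' rate below 60 bpm) and `high` when samples exceed the upper threshold
#' (heart rate above 100 bpm; SpO2 has no upper rule). The statistic is the
#' block minimum (low) or maximum (high). One block can yield both a low and
#' a high heart-rate flag. Comparisons are strict: boundary values never
#' flag.
#'
#' @param series SpO2 or heart-rate [channel_series()].
#' @param day One-row day window.
#' @param cfg A [threshold_config()].
#' @return Data frame of violation blocks as in [flag_activity_blocks()].
#' @export
flag_range_blocks <- function(series, day, cfg = threshold_config()) {
  if (!series$channel %in% c("spo2", "heart_rate")) {
    stop("series must be the spo2 or heart_rate channel")
  }
  lo <- if (series$channel == "spo2") cfg$spo2_low else cfg$hr_low
  hi <- if (series$channel == "spo2") NA_real_ else cfg$hr_high
  s <- sort_series(series)
  keep <- s$t >= day$start & s$t < day$end
  t <- s$t[keep]; v <- s$value[keep]
  tz <- attr(day$start, "tzone")
  if (length(t) == 0L) return(empty_blocks(tz))
  bw <- cfg$block_minutes * 60
  idx <- floor((as.numeric(t) - as.numeric(day$start)) / bw)
  st <- block_stats(idx, v)
  out <- list(empty_blocks(tz))
  n_low <- block_count_if(idx, v < lo)
  hit <- n_low >= cfg$min_violation_samples
  if (any(hit)) {
    out <- c(out, list(data.frame(
      channel = series$channel, kind = "low",
      start = day$start + st$block[hit] * bw,
      end = day$start + (st$block[hit] + 1) * bw,
      statistic = st$min[hit], n_samples = as.integer(st$n[hit]))))
  }
  if (!is.na(hi)) {
    n_high <- block_count_if(idx, v > hi)
    hit <- n_high >= cfg$min_violation_samples
    if (any(hit)) {
      out <- c(out, list(data.frame(
        channel = series$channel, kind = "high",
        start = day$start + st$block[hit] * bw,
        end = day$start + (st$block[hit] + 1) * bw,
        statistic = st$max[hit], n_samples = as.integer(st$n[hit]))))
    }
  }
  res <- do.call(rbind, out)
  res[order(res$start, res$kind), , drop = FALSE]
}

#' Summarize one clinical day
#'
#' Deterministic aggregation of the per-day analyses: sleeping period, wear
#' intervals, all violation blocks, and the day's episodic entries. Violation
#' blocks are restricted to grid intervals overlapping the sleeping period,
#' since Layer 2 shows sleeping-period details only -- a daytime activity
#' bout outside the sleep span is not reported. A day with no data yields an
#' empty summary with `sleep = NULL`.
#'
#' @param record A [patient_record()].
#' @param day One-row day window (or a day index).
#' @param cfg A [threshold_config()].
#' @return An object of class `day_summary` with fields `day_index`, `day`,
#'   `sleep`, `wear`, `blocks`, `episodic`, `cfg`.
#' @export
summarize_day <- function(record, day, cfg = threshold_config()) {
  if (is.numeric(day)) day <- day_window(record, day)
  sleep <- detect_sleep_period(record, day, slot_minutes = cfg$block_minutes)
  wear <- detect_wear(record, day)
  blocks <- empty_blocks(attr(day$start, "tzone"))
  if (!is.null(sleep)) {
    parts <- list(blocks)
    for (ch in c("spo2", "heart_rate")) {
      s <- record$channels[[ch]]
      if (!is.null(s)) parts <- c(parts, list(flag_range_blocks(s, day, cfg)))
    }
    if (!is.null(record$channels$activity)) {
      parts <- c(parts,
                 list(flag_activity_blocks(record$channels$activity, day, cfg)))
    }
    blocks <- do.call(rbind, parts)
    overlaps <- blocks$start < sleep$end & blocks$end > sleep$start
    blocks <- blocks[overlaps, , drop = FALSE]
    ord <- order(match(blocks$channel, names(CHANNEL_UNITS)),
                 blocks$start, blocks$kind)
    blocks <- blocks[ord, , drop = FALSE]
    rownames(blocks) <- NULL
  }
  epi <- Filter(function(m) m$t >= day$start && m$t < day$end, record$episodic)
  structure(
    list(day_index = day$index, day = day, sleep = sleep, wear = wear,
         blocks = blocks, episodic = epi, cfg = cfg),
    class = "day_summary"
  )
}

#' @export
print.day_summary <- function(x, ...) {
  cat(sprintf("<day_summary> day %d: sleep %s, %d wear interval(s), %d violation block(s), %d episodic\n",
              x$day_index,
              if (is.null(x$sleep)) "none"
              else paste(format(x$sleep$start, "%H:%M"), "-",
                         format(x$sleep$end, "%H:%M")),
              nrow(x$wear$intervals), nrow(x$blocks), length(x$episodic)))
  invisible(x)
}

#' Export a day summary as JSON
#'
#' Machine-readable form of [summarize_day()] output (sleeping period, wear
#' intervals, violation blocks with channel/kind/statistic) for downstream
#' rendering and testing.
#'
#' @param summary A `day_summary`.
#' @param path Optional output file; when `NULL` the JSON text is returned.
#' @return JSON text (invisibly when written to `path`).
#' @export
day_summary_json <- function(summary, path = NULL) {
  obj <- list(
    day_index = summary$day_index,
    day = list(start = fmt_iso(summary$day$start),
               end = fmt_iso(summary$day$end)),
    sleep = if (is.null(summary$sleep)) NULL else
      list(start = fmt_iso(summary$sleep$start),
           end = fmt_iso(summary$sleep$end)),
    wear = if (nrow(summary$wear$intervals)) data.frame(
      start = fmt_iso(summary$wear$intervals$start),
      end = fmt_iso(summary$wear$intervals$end)) else list(),
    blocks = if (nrow(summary$blocks)) data.frame(
      channel = summary$blocks$channel, kind = summary$blocks$kind,
      start = fmt_iso(summary$blocks$start), end = fmt_iso(summary$blocks$end),
      statistic = summary$blocks$statistic,
      n_samples = summary$blocks$n_samples) else list()
  )
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}
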