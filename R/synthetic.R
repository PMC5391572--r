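# Seeded synthetic six-night records of nocturnal heart-failure physiology.
# Signals are piecewise-constant baselines + Gaussian jitter + trapezoidal
# event excursions (desaturations, brady/tachycardia, activity bouts); no
# physiological ODE model -- the generator exists to exercise detection and
# rendering logic with a known ground truth, not to simulate cardiopulmonary
# dynamics. Nights are placed inside 4 pm-to-4 pm windows so day partitioning
# is exercised across midnight; Bernoulli per-sample dropout plus occasional
# long gaps exercise wear-period detection.

#' Generator configuration
#'
#' Defaults emulate a six-night home-monitoring study of a heart-failure
#' patient: sleep onset around 23:00 (SD 30 min) lasting about 7 h; SpO2
#' baseline 96% with 0.5% sample jitter and ~3 desaturation events per night
#' dipping to 85-91% for 60-300 s; heart-rate baseline 72 bpm (SD 2) with
#' one bradycardia (45-58 bpm) and one tachycardia (102-115 bpm) episode per
#' night; ~2 nocturnal out-of-bed activity bouts per night (5-25 min at
#' 20-60 vector magnitude units, so 30-min block means straddle the
#' real-activity threshold);
#' 2% sample dropout plus occasional long gaps; daily weight with a slow
#' upward drift (fluid retention), two blood-pressure readings per day and
#' one evening subjective-state entry.
#'
#' @param seed Integer seed; identical configs give identical output.
#' @param n_nights Number of nights (default 6).
#' @param start_date First clinical day's date (`YYYY-mm-dd`); Day 1 starts
#'   at 16:00 local on this date.
#' @param tz Record timezone.
#' @param patient_id,display_name Identity of the synthetic patient.
#' @param sleep_start_mean Mean sleep-onset clock time (`"HH:MM"`).
#' @param sleep_start_sd_min SD of sleep onset, minutes.
#' @param sleep_duration_mean_h,sleep_duration_sd_h Sleep duration, hours.
#' @param spo2_baseline_mean,spo2_baseline_sd SpO2 baseline and per-sample
#'   jitter SD, percent.
#' @param desat_events_per_night Planted desaturations per night.
#' @param desat_depth_range Desaturation nadir range, percent.
#' @param desat_duration_range Desaturation duration range, seconds.
#' @param hr_baseline_mean,hr_baseline_sd Heart-rate baseline and jitter, bpm.
#' @param brady_events_per_night,tachy_events_per_night Cardiac episodes per
#'   night.
#' @param brady_range,tachy_range Episode plateau ranges, bpm.
#' @param cardiac_duration_range Cardiac episode duration range, seconds.
#' @param activity_bouts_per_night Activity bouts per night (some may be
#'   planted in the daytime remainder of the window when `daytime_bouts`).
#' @param activity_intensity_range Bout plateau range, vector magnitude units.
#' @param activity_duration_range Bout duration range, seconds.
#' @param activity_baseline_mean,activity_baseline_sd Resting activity noise.
#' @param gap_rate Bernoulli per-sample dropout fraction.
#' @param long_gap_prob Probability of one long gap per night.
#' @param long_gap_range Long-gap duration range, seconds.
#' @param weight_start_kg,weight_daily_drift_kg Weight trajectory.
#' @param bp_systolic_mean,bp_systolic_sd,bp_diastolic_mean,bp_diastolic_sd
#'   Blood-pressure reading distribution, mmHg.
#' @param bp_readings_per_day Blood-pressure readings per day.
#' @param subjective_range Range of the subjective summary score.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(seed = 1L, n_nights = 6L,
                             start_date = "2016-01-04", tz = "UTC",
                             patient_id = "synthetic-001",
                             display_name = "Synthetic Patient",
                             sleep_start_mean = "23:00",
                             sleep_start_sd_min = 30,
                             sleep_duration_mean_h = 7,
                             sleep_duration_sd_h = 0.75,
                             spo2_baseline_mean = 96, spo2_baseline_sd = 0.5,
                             desat_events_per_night = 3L,
                             desat_depth_range = c(85, 91),
                             desat_duration_range = c(60, 300),
                             hr_baseline_mean = 72, hr_baseline_sd = 2,
                             brady_events_per_night = 1L,
                             tachy_events_per_night = 1L,
                             brady_range = c(45, 58),
                             tachy_range = c(102, 115),
                             cardiac_duration_range = c(60, 300),
                             activity_bouts_per_night = 2L,
                             activity_intensity_range = c(20, 60),
                             activity_duration_range = c(300, 1500),
                             activity_baseline_mean = 1,
                             activity_baseline_sd = 1,
                             gap_rate = 0.02,
                             long_gap_prob = 0.5,
                             long_gap_range = c(120, 900),
                             weight_start_kg = 82,
                             weight_daily_drift_kg = 0.3,
                             bp_systolic_mean = 125, bp_systolic_sd = 8,
                             bp_diastolic_mean = 78, bp_diastolic_sd = 6,
                             bp_readings_per_day = 2L,
                             subjective_range = c(0, 10)) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_nights >= 1L,
            cfg$sleep_start_sd_min >= 0, cfg$sleep_duration_sd_h >= 0,
            cfg$spo2_baseline_sd >= 0, cfg$hr_baseline_sd >= 0,
            diff(cfg$desat_depth_range) >= 0,
            diff(cfg$desat_duration_range) >= 0,
            diff(cfg$brady_range) >= 0, diff(cfg$tachy_range) >= 0,
            diff(cfg$activity_intensity_range) >= 0,
            cfg$gap_rate >= 0, cfg$gap_rate < 1)
  structure(cfg, class = "generator_config")
}

# Trapezoidal excursion profile over per-second offsets 0..(dur-1): ramps up
# over ramp_frac of the duration, holds, ramps down.
#' @keywords internal
#' @noRd
trapezoid <- function(dur, ramp_frac = 0.15) {
  x <- seq_len(dur) - 1
  ramp <- max(1, floor(dur * ramp_frac))
  up <- pmin(1, x / ramp)
  down <- pmin(1, (dur - 1 - x) / ramp)
  pmin(up, down)
}

# Draw `n` non-overlapping event windows (start offsets, durations in s)
# inside [0, span); gives up on candidates that keep colliding.
#' @keywords internal
#' @noRd
place_events <- function(n, span, dur_range) {
  if (n == 0L || span <= dur_range[1]) {
    return(data.frame(offset = numeric(0), dur = numeric(0)))
  }
  placed <- data.frame(offset = numeric(0), dur = numeric(0))
  for (i in seq_len(n)) {
    for (try in 1:50) {
      dur <- round(stats::runif(1, dur_range[1], min(dur_range[2], span)))
      off <- round(stats::runif(1, 0, span - dur))
      ok <- !any(off < placed$offset + placed$dur & off + dur > placed$offset)
      if (ok) {
        placed <- rbind(placed, data.frame(offset = off, dur = dur))
        break
      }
    }
  }
  placed[order(placed$offset), , drop = FALSE]
}

# Independent naive scan used to derive the ground-truth expected block set:
# for each clinical day, find the first/last 30-min slot holding any SpO2 or
# heart-rate sample, then walk every grid block overlapping that span and
# apply the threshold rules sample by sample. Deliberately simple and
# separate from the detection module's vectorized path.
#' @keywords internal
#' @noRd
naive_expected_blocks <- function(record, thr = threshold_config()) {
  bw <- thr$block_minutes * 60
  rows <- list()
  get <- function(ch) {
    s <- record$channels[[ch]]
    if (is.null(s)) list(t = numeric(0), v = numeric(0))
    else list(t = as.numeric(s$t), v = s$value)
  }
  spo2 <- get("spo2"); hr <- get("heart_rate"); act <- get("activity")
  for (d in seq_len(nrow(record$days))) {
    d0 <- as.numeric(record$days$start[d]); d1 <- as.numeric(record$days$end[d])
    # restrict each channel to this day before the per-block scan
    in_day <- function(x) {
      keep <- x$t >= d0 & x$t < d1
      list(t = x$t[keep], v = x$v[keep])
    }
    spo2_d <- in_day(spo2); hr_d <- in_day(hr); act_d <- in_day(act)
    slot_t <- c(spo2_d$t, hr_d$t)
    if (length(slot_t) == 0L) next
    sleep_lo <- d0 + floor(min((slot_t - d0)) / bw) * bw
    sleep_hi <- d0 + (floor(max((slot_t - d0)) / bw) + 1) * bw
    for (b0 in seq(d0, d1 - bw, by = bw)) {
      b1 <- b0 + bw
      if (!(b0 < sleep_hi && b1 > sleep_lo)) next
      sv <- spo2_d$v[spo2_d$t >= b0 & spo2_d$t < b1]
      if (sum(sv < thr$spo2_low) >= thr$min_violation_samples) {
        rows[[length(rows) + 1L]] <- data.frame(
          day_index = d, channel = "spo2", kind = "low", start = b0)
      }
      hv <- hr_d$v[hr_d$t >= b0 & hr_d$t < b1]
      if (sum(hv < thr$hr_low) >= thr$min_violation_samples) {
        rows[[length(rows) + 1L]] <- data.frame(
          day_index = d, channel = "heart_rate", kind = "low", start = b0)
      }
      if (sum(hv > thr$hr_high) >= thr$min_violation_samples) {
        rows[[length(rows) + 1L]] <- data.frame(
          day_index = d, channel = "heart_rate", kind = "high", start = b0)
      }
      av <- act_d$v[act_d$t >= b0 & act_d$t < b1]
      if (length(av) && mean(av) > thr$activity_high) {
        rows[[length(rows) + 1L]] <- data.frame(
          day_index = d, channel = "activity", kind = "high", start = b0)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(day_index = integer(0), channel = character(0),
                      kind = character(0), start = numeric(0)))
  }
  out <- do.call(rbind, rows)
  out$start <- as.POSIXct(out$start, tz = record$tz, origin = "1970-01-01")
  out[order(out$day_index, out$channel, out$start, out$kind), , drop = FALSE]
}

#' Generate a synthetic patient record with ground truth
#'
#' Produces 1 Hz SpO2 / heart-rate / activity samples over each night's sleep
#' interval (with dropout gaps), daily weight, blood-pressure readings and an
#' evening subjective entry, plus a ground-truth log of every planted event
#' and the set of grid blocks that must flag under the supplied thresholds.
#' Events falling partly outside the sleep window are clipped (and logged as
#' clipped). Output is fully determined by the config, including its seed.
#'
#' Expected blocks are derived from the final generated samples by an
#' independent naive per-sample scan, not from the event geometry: with
#' trapezoidal ramps plus jitter, geometry alone cannot decide borderline
#' blocks.
#'
#' @param cfg A [generator_config()].
#' @param thresholds [threshold_config()] under which the expected block set
#'   is computed.
#' @return List with `record` (a [patient_record()]) and `ground_truth`
#'   (class `ground_truth_log`: `events` data frame and `expected_blocks`
#'   data frame with `day_index`, `channel`, `kind`, `start`).
#' @export
generate_record <- function(cfg = generator_config(),
                            thresholds = threshold_config()) {
  set.seed(cfg$seed)
  tz <- cfg$tz
  day1 <- as.POSIXct(paste(cfg$start_date, "16:00:00"), tz = tz)
  days <- data.frame(index = seq_len(cfg$n_nights),
                     start = day1 + (seq_len(cfg$n_nights) - 1L) * 86400,
                     end = day1 + seq_len(cfg$n_nights) * 86400)

  onset_off <- clock_to_seconds(cfg$sleep_start_mean) - 16 * 3600
  if (onset_off < 0) onset_off <- onset_off + 86400

  spo2_t <- spo2_v <- hr_t <- hr_v <- act_t <- act_v <- list()
  events <- list()
  episodic <- list()

  for (night in seq_len(cfg$n_nights)) {
    d0 <- as.numeric(days$start[night])
    onset <- d0 + onset_off + stats::rnorm(1, 0, cfg$sleep_start_sd_min * 60)
    dur <- stats::rnorm(1, cfg$sleep_duration_mean_h,
                        cfg$sleep_duration_sd_h) * 3600
    onset <- round(max(d0, min(onset, d0 + 86400 - 3600)))
    sleep_end <- round(min(onset + max(dur, 3600), d0 + 86400))
    span <- sleep_end - onset
    tt <- onset + seq_len(span) - 1  # per-second grid over the night

    log_event <- function(channel, type, off, dur, magnitude, clipped) {
      events[[length(events) + 1L]] <<- data.frame(
        night = night, channel = channel, type = type,
        start = onset + off, end = onset + off + dur,
        magnitude = magnitude, clipped = clipped)
    }

    # SpO2: baseline + jitter + desaturation dips
    v <- cfg$spo2_baseline_mean + stats::rnorm(span, 0, cfg$spo2_baseline_sd)
    ev <- place_events(cfg$desat_events_per_night, span, cfg$desat_duration_range)
    for (i in seq_len(nrow(ev))) {
      depth <- stats::runif(1, cfg$desat_depth_range[1], cfg$desat_depth_range[2])
      idx <- ev$offset[i] + seq_len(ev$dur[i])
      clipped <- any(idx > span)
      idx <- idx[idx <= span]
      v[idx] <- v[idx] + (depth - cfg$spo2_baseline_mean) *
        trapezoid(ev$dur[i])[seq_along(idx)]
      log_event("spo2", "desaturation", ev$offset[i], ev$dur[i], depth, clipped)
    }
    v <- pmin(pmax(v, 0), 100)
    spo2_t[[night]] <- tt; spo2_v[[night]] <- round(v, 1)

    # Heart rate: baseline + jitter + brady/tachy plateaus
    v <- cfg$hr_baseline_mean + stats::rnorm(span, 0, cfg$hr_baseline_sd)
    ev <- place_events(cfg$brady_events_per_night + cfg$tachy_events_per_night,
                       span, cfg$cardiac_duration_range)
    types <- rep(c("bradycardia", "tachycardia"),
                 c(cfg$brady_events_per_night, cfg$tachy_events_per_night))
    types <- types[seq_len(nrow(ev))]
    for (i in seq_len(nrow(ev))) {
      level <- if (types[i] == "bradycardia") {
        stats::runif(1, cfg$brady_range[1], cfg$brady_range[2])
      } else {
        stats::runif(1, cfg$tachy_range[1], cfg$tachy_range[2])
      }
      idx <- ev$offset[i] + seq_len(ev$dur[i])
      clipped <- any(idx > span)
      idx <- idx[idx <= span]
      v[idx] <- v[idx] + (level - cfg$hr_baseline_mean) *
        trapezoid(ev$dur[i])[seq_along(idx)]
      log_event("heart_rate", types[i], ev$offset[i], ev$dur[i], level, clipped)
    }
    v <- pmax(v, 0)
    hr_t[[night]] <- tt; hr_v[[night]] <- round(v, 1)

    # Activity: low resting noise + bouts
    v <- abs(stats::rnorm(span, cfg$activity_baseline_mean,
                          cfg$activity_baseline_sd))
    ev <- place_events(cfg$activity_bouts_per_night, span,
                       cfg$activity_duration_range)
    for (i in seq_len(nrow(ev))) {
      level <- stats::runif(1, cfg$activity_intensity_range[1],
                            cfg$activity_intensity_range[2])
      idx <- ev$offset[i] + seq_len(ev$dur[i])
      clipped <- any(idx > span)
      idx <- idx[idx <= span]
      v[idx] <- v[idx] + level * trapezoid(ev$dur[i])[seq_along(idx)]
      log_event("activity", "bout", ev$offset[i], ev$dur[i], level, clipped)
    }
    act_t[[night]] <- tt; act_v[[night]] <- round(pmax(v, 0), 2)

    # Dropout: Bernoulli deletions shared per channel draw; occasional long gap
    for (ch in c("spo2", "hr", "act")) {
      tl <- get(paste0(ch, "_t")); vl <- get(paste0(ch, "_v"))
      keep <- stats::runif(span) >= cfg$gap_rate
      if (stats::runif(1) < cfg$long_gap_prob) {
        glen <- round(stats::runif(1, cfg$long_gap_range[1],
                                   cfg$long_gap_range[2]))
        g0 <- round(stats::runif(1, 0, max(1, span - glen)))
        keep[g0 + seq_len(min(glen, span - g0))] <- FALSE
      }
      tl[[night]] <- tl[[night]][keep]
      vl[[night]] <- vl[[night]][keep]
      assign(paste0(ch, "_t"), tl); assign(paste0(ch, "_v"), vl)
    }

    # Episodic entries for this clinical day
    wt_t <- d0 + 15.5 * 3600 + round(stats::rnorm(1, 0, 600))  # ~07:30 next am
    episodic[[length(episodic) + 1L]] <- episodic_measurement(
      "weight", as.POSIXct(wt_t, tz = tz, origin = "1970-01-01"),
      weight_kg = round(cfg$weight_start_kg +
                          (night - 1) * cfg$weight_daily_drift_kg +
                          stats::rnorm(1, 0, 0.2), 1))
    bp_offsets <- seq(2 * 3600, 15 * 3600,
                      length.out = max(1L, cfg$bp_readings_per_day))
    for (off in bp_offsets) {
      sys <- round(stats::rnorm(1, cfg$bp_systolic_mean, cfg$bp_systolic_sd))
      dia <- round(stats::rnorm(1, cfg$bp_diastolic_mean, cfg$bp_diastolic_sd))
      if (dia >= sys) dia <- sys - 10
      episodic[[length(episodic) + 1L]] <- episodic_measurement(
        "blood_pressure",
        as.POSIXct(d0 + off + round(stats::rnorm(1, 0, 900)), tz = tz,
                   origin = "1970-01-01"),
        systolic_mmhg = sys, diastolic_mmhg = max(dia, 40))
    }
    items <- c(breathlessness = NA, fatigue = NA, swelling = NA,
               sleep_quality = NA, mood = NA)
    items[] <- round(stats::runif(length(items), cfg$subjective_range[1],
                                  cfg$subjective_range[2]), 1)
    episodic[[length(episodic) + 1L]] <- episodic_measurement(
      "subjective",
      as.POSIXct(d0 + 5 * 3600 + round(stats::rnorm(1, 0, 1200)), tz = tz,
                 origin = "1970-01-01"),
      subjective_score = round(mean(items), 1), subjective_items = items)
  }

  mk <- function(ch, tl, vl) {
    t <- as.POSIXct(unlist(tl), tz = tz, origin = "1970-01-01")
    channel_series(ch, t, unlist(vl))
  }
  record <- patient_record(
    patient_id = cfg$patient_id, display_name = cfg$display_name,
    channels = list(mk("spo2", spo2_t, spo2_v),
                    mk("heart_rate", hr_t, hr_v),
                    mk("activity", act_t, act_v)),
    episodic = episodic[order(vapply(episodic, function(m) as.numeric(m$t),
                                     numeric(1)))],
    days = days, tz = tz)

  ev <- if (length(events)) do.call(rbind, events) else
    data.frame(night = integer(0), channel = character(0), type = character(0),
               start = numeric(0), end = numeric(0), magnitude = numeric(0),
               clipped = logical(0))
  if (nrow(ev)) {
    ev$start <- as.POSIXct(ev$start, tz = tz, origin = "1970-01-01")
    ev$end <- as.POSIXct(ev$end, tz = tz, origin = "1970-01-01")
  }
  gt <- structure(
    list(events = ev,
         expected_blocks = naive_expected_blocks(record, thresholds),
         thresholds = thresholds),
    class = "ground_truth_log")
  list(record = record, ground_truth = gt)
}

#' Write a ground-truth log as JSON
#'
#' @param gt A `ground_truth_log` from [generate_record()].
#' @param path Optional output file.
#' @return JSON text (invisibly when written).
#' @export
ground_truth_json <- function(gt, path = NULL) {
  obj <- list(
    events = if (nrow(gt$events)) data.frame(
      night = gt$events$night, channel = gt$events$channel,
      type = gt$events$type, start = fmt_iso(gt$events$start),
      end = fmt_iso(gt$events$end), magnitude = gt$events$magnitude,
      clipped = gt$events$clipped) else list(),
    expected_blocks = if (nrow(gt$expected_blocks)) data.frame(
      day_index = gt$expected_blocks$day_index,
      channel = gt$expected_blocks$channel,
      kind = gt$expected_blocks$kind,
      start = fmt_iso(gt$expected_blocks$start)) else list()
  )
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Generate SUS questionnaires targeting a mean and SD
#'
#' Produces integer 1..5 Likert response sets whose transformed 0-100 SUS
#' scores have sample mean and SD close to the targets (mean within 0.15,
#' SD within 0.2; well inside the ±1-point contract). Respondent scores are
#' drawn from a normal, standardized to the targets, snapped to the 2.5-point
#' SUS grid and clipped to \[0, 100\], then refined by a deterministic
#' hill-climb on single-respondent ±2.5 moves. Each score is realized as an
#' item pattern by distributing its contribution total over the ten items in
#' a seeded random order. Fully reproducible by seed.
#'
#' @param n Number of respondents.
#' @param target_mean Target sample mean of the transformed scores, 0-100.
#' @param target_sd Target sample SD of the transformed scores.
#' @param seed Integer seed.
#' @return List of `sus_response` objects.
#' @export
generate_sus_responses <- function(n, target_mean, target_sd, seed = 1L) {
  if (n < 1L) stop("n must be >= 1")
  if (target_mean < 0 || target_mean > 100) stop("target_mean must be in [0,100]")
  if (target_sd < 0) stop("target_sd must be >= 0")
  if (target_sd > 0 && (target_mean >= 100 || target_mean <= 0)) {
    stop("infeasible target: boundary mean with positive sd")
  }
  # population-variance bound for values confined to [0, 100]
  if (target_sd > sqrt(target_mean * (100 - target_mean)) + 1e-9) {
    stop("infeasible target: sd too large for a [0,100]-bounded score")
  }
  set.seed(seed)

  snap <- function(x) pmin(100, pmax(0, round(x / 2.5) * 2.5))
  objective <- function(s) {
    dm <- mean(s) - target_mean
    dsd <- if (n > 1L) stats::sd(s) - target_sd else 0
    abs(dm) / 0.15 + abs(dsd) / 0.2
  }
  ok <- function(s) {
    (abs(mean(s) - target_mean) <= 0.15) &&
      (n == 1L || target_sd == 0 || abs(stats::sd(s) - target_sd) <= 0.2)
  }

  scores <- NULL
  if (target_sd == 0) {
    scores <- rep(snap(target_mean), n)
    if (abs(scores[1] - target_mean) > 1) {
      stop("infeasible target: zero sd off the 2.5-point score grid")
    }
  } else {
    for (attempt in 1:50) {
      z <- stats::rnorm(n)
      s <- snap(target_mean + (z - mean(z)) / stats::sd(z) * target_sd)
      # hill-climb: best single ±2.5 move until within tolerance or stuck
      for (step in 1:5000) {
        if (ok(s)) break
        best <- NULL; best_obj <- objective(s)
        for (i in seq_len(n)) for (d in c(-2.5, 2.5)) {
          cand <- s
          cand[i] <- cand[i] + d
          if (cand[i] < 0 || cand[i] > 100) next
          o <- objective(cand)
          if (o < best_obj - 1e-12) { best <- cand; best_obj <- o }
        }
        if (is.null(best)) break
        s <- best
      }
      if (ok(s)) { scores <- s; break }
    }
    if (is.null(scores)) {
      stop("could not realize target mean/sd within the ±1-point tolerance")
    }
  }

  lapply(seq_len(n), function(i) {
    contrib_total <- round(scores[i] / 2.5)  # 0..40
    q <- contrib_total %/% 10L
    r <- contrib_total %% 10L
    contrib <- rep(q, 10L)
    if (r > 0L) contrib[sample.int(10L, r)] <- q + 1L
    items <- integer(10L)
    odd <- seq(1L, 9L, by = 2L)
    items[odd] <- contrib[odd] + 1L
    items[-odd] <- 5L - contrib[-odd]
    sus_response(sprintf("synthetic-%02d", i), items)
  })
}
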