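# Shared fixtures and independent oracles. The oracles re-derive expected
# results by brute force (per-sample scans, per-item enumeration, from-scratch
# ANOVA) and never call the code paths they check.

utc <- function(x) as.POSIXct(x, tz = "UTC")

# A one-night record built by hand: night of day 1 (start 2016-01-04 16:00).
make_series <- function(channel, start, n, value, by = 1) {
  t <- utc(start) + seq_len(n) * by - by
  channel_series(channel, t, rep_len(value, n))
}

make_day <- function(start = "2016-01-04 16:00:00") {
  s <- utc(start)
  data.frame(index = 1L, start = s, end = s + 86400)
}

make_record <- function(channels = list(), episodic = list(),
                        start = "2016-01-04 16:00:00", n_days = 1L) {
  s <- utc(start)
  days <- data.frame(index = seq_len(n_days),
                     start = s + (seq_len(n_days) - 1L) * 86400,
                     end = s + seq_len(n_days) * 86400)
  patient_record("test-001", "Test Patient", channels = channels,
                 episodic = episodic, days = days, tz = "UTC")
}

# Brute-force violation-block oracle: scans every grid block sample by
# sample. Independent of both the detection module and the generator's
# ground-truth scan.
oracle_blocks <- function(record, day, cfg = threshold_config()) {
  bw <- cfg$block_minutes * 60
  d0 <- as.numeric(day$start)
  rows <- list()
  for (b in seq_len(1440 %/% cfg$block_minutes)) {
    b0 <- d0 + (b - 1) * bw; b1 <- b0 + bw
    for (ch in names(record$channels)) {
      s <- record$channels[[ch]]
      v <- s$value[as.numeric(s$t) >= b0 & as.numeric(s$t) < b1]
      if (!length(v)) next
      if (ch == "spo2" && sum(v < cfg$spo2_low) >= cfg$min_violation_samples) {
        rows[[length(rows) + 1L]] <- c(ch, "low", b0)
      }
      if (ch == "heart_rate") {
        if (sum(v < cfg$hr_low) >= cfg$min_violation_samples) {
          rows[[length(rows) + 1L]] <- c(ch, "low", b0)
        }
        if (sum(v > cfg$hr_high) >= cfg$min_violation_samples) {
          rows[[length(rows) + 1L]] <- c(ch, "high", b0)
        }
      }
      if (ch == "activity" && mean(v) > cfg$activity_high) {
        rows[[length(rows) + 1L]] <- c(ch, "high", b0)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(channel = character(0), kind = character(0),
                      start = numeric(0)))
  }
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(df) <- c("channel", "kind", "start")
  df$start <- as.numeric(df$start)
  df[order(df$channel, df$start, df$kind), , drop = FALSE]
}

# Canonical key for comparing flag sets.
block_key <- function(channel, kind, start) {
  sort(paste(channel, kind, as.numeric(start)))
}

# Brute-force SUS scorer: explicit per-item contribution table, no shared
# arithmetic with score_sus beyond the published weightings.
oracle_sus <- function(items) {
  contrib <- vapply(1:10, function(i) {
    if (i %% 2 == 1) items[i] - 1 else 5 - items[i]
  }, numeric(1))
  c(overall = 2.5 * sum(contrib),
    usability = 3.125 * sum(contrib[c(1, 2, 3, 5, 6, 7, 9, 10)]),
    learnability = 12.5 * sum(contrib[c(4, 8)]))
}

# From-scratch two-way ANOVA decomposition for the ICC oracle: explicit
# double loops over cells.
oracle_icc31 <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- sum(m) / (n * k)
  ss_rows <- 0
  for (i in seq_len(n)) ss_rows <- ss_rows + k * (mean(m[i, ]) - grand)^2
  ss_cols <- 0
  for (j in seq_len(k)) ss_cols <- ss_cols + n * (mean(m[, j]) - grand)^2
  ss_err <- 0
  for (i in seq_len(n)) for (j in seq_len(k)) {
    ss_err <- ss_err + (m[i, j] - mean(m[i, ]) - mean(m[, j]) + grand)^2
  }
  bms <- ss_rows / (n - 1)
  ems <- ss_err / ((n - 1) * (k - 1))
  (bms - ems) / (bms + (k - 1) * ems)
}
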