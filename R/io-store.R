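# File-backed store. One directory per patient holding exactly two tables --
# continuous.csv (timestamp,channel,value) and episodic.csv
# (timestamp,kind,key,value in long form) -- plus manifest.json. The
# episodic/continuous split mirrors the two-table-per-patient schema the
# display was designed around; continuous and episodic rows never share a
# file.

#' Read a device channel export
#'
#' Reads a CSV with header `timestamp,value` into a [channel_series()].
#' Timestamps may be ISO-8601 with offset or `YYYY-mm-dd HH:MM:SS` (taken in
#' `tz`). Rows are sorted by time; duplicated timestamps (device
#' re-transmission artifacts) are collapsed to their mean value with a
#' warning rather than aborting ingestion. An empty file with a valid header
#' yields an empty series.
#'
#' @param path CSV file path.
#' @param channel Target channel (`"spo2"`, `"heart_rate"`, `"activity"`).
#' @param tz Timezone for offset-less timestamps.
#' @return A [channel_series()].
#' @export
read_channel_csv <- function(path, channel, tz = "UTC") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("timestamp", "value") %in% names(df))) {
    stop("format error: ", path, " must have header columns timestamp,value")
  }
  if (nrow(df) == 0L) {
    return(channel_series(channel, as.POSIXct(character(0), tz = tz), numeric(0)))
  }
  t <- parse_iso(df$timestamp, tz = tz)
  if (anyNA(t)) {
    bad <- which(is.na(t))[1L]
    stop(sprintf("unparseable timestamp %s at line %d of %s",
                 df$timestamp[bad], bad + 1L, path))
  }
  value <- suppressWarnings(as.numeric(df$value))
  if (anyNA(value)) {
    bad <- which(is.na(value))[1L]
    stop(sprintf("unparseable value %s at line %d of %s",
                 df$value[bad], bad + 1L, path))
  }
  o <- order(t)
  t <- t[o]; value <- value[o]
  key <- as.numeric(t)
  if (anyDuplicated(key)) {
    warning(sprintf("%s: %d duplicated timestamp(s) collapsed to mean value",
                    path, sum(duplicated(key))))
    value <- as.numeric(tapply(value, key, mean))
    t <- as.POSIXct(unique(key), tz = tz, origin = "1970-01-01")
  }
  channel_series(channel, t, value)
}

#' @keywords internal
#' @noRd
num_chr <- function(x) format(x, digits = 15, scientific = FALSE, trim = TRUE)

#' @keywords internal
#' @noRd
episodic_to_long <- function(episodic) {
  rows <- lapply(episodic, function(m) {
    payload <- switch(
      m$kind,
      weight = c(weight_kg = m$weight_kg),
      blood_pressure = c(systolic_mmhg = m$systolic_mmhg,
                         diastolic_mmhg = m$diastolic_mmhg),
      subjective = {
        items <- m$subjective_items
        v <- c(score = m$subjective_score,
               if (length(items)) stats::setNames(as.numeric(items),
                                                  paste0("item:", names(items))))
        v
      })
    data.frame(timestamp = fmt_iso(m$t), kind = m$kind,
               key = names(payload), value = num_chr(as.numeric(payload)),
               stringsAsFactors = FALSE)
  })
  if (!length(rows)) {
    return(data.frame(timestamp = character(0), kind = character(0),
                      key = character(0), value = character(0)))
  }
  do.call(rbind, rows)
}

#' @keywords internal
#' @noRd
long_to_episodic <- function(df, tz) {
  if (nrow(df) == 0L) return(list())
  grp <- paste(df$timestamp, df$kind, sep = "\r")
  out <- lapply(split(seq_len(nrow(df)), factor(grp, levels = unique(grp))),
                function(idx) {
    sub <- df[idx, , drop = FALSE]
    t <- parse_iso(sub$timestamp[1L], tz = tz)
    kind <- sub$kind[1L]
    val <- stats::setNames(as.numeric(sub$value), sub$key)
    switch(
      kind,
      weight = episodic_measurement("weight", t, weight_kg = val[["weight_kg"]]),
      blood_pressure = episodic_measurement(
        "blood_pressure", t,
        systolic_mmhg = val[["systolic_mmhg"]],
        diastolic_mmhg = val[["diastolic_mmhg"]]),
      subjective = {
        is_item <- startsWith(names(val), "item:")
        items <- val[is_item]
        names(items) <- sub("^item:", "", names(items))
        episodic_measurement("subjective", t,
                             subjective_score = val[["score"]],
                             subjective_items = items)
      },
      stop("unknown episodic kind in store: ", kind))
  })
  unname(out)
}

#' Write a patient record to a file-backed store
#'
#' Creates `dir/<patient_id>/` with `continuous.csv`, `episodic.csv` and
#' `manifest.json`. The episodic table is written even when empty. Timestamps
#' are serialized as ISO-8601 with offset; [read_store()] of the result
#' reproduces the record (timestamps to 1 s, values to stored precision).
#'
#' @param record A valid [patient_record()].
#' @param dir Store root directory (created if missing).
#' @return Invisibly, the patient directory path.
#' @export
write_store <- function(record, dir) {
  pdir <- file.path(dir, record$patient_id)
  dir.create(pdir, recursive = TRUE, showWarnings = FALSE)
  cont <- do.call(rbind, c(lapply(record$channels, function(s) {
    data.frame(timestamp = fmt_iso(s$t), channel = s$channel,
               value = num_chr(s$value), stringsAsFactors = FALSE)
  }), list(make.row.names = FALSE)))
  if (is.null(cont)) {
    cont <- data.frame(timestamp = character(0), channel = character(0),
                       value = character(0))
  }
  utils::write.csv(cont, file.path(pdir, "continuous.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(episodic_to_long(record$episodic),
                   file.path(pdir, "episodic.csv"), row.names = FALSE,
                   quote = FALSE)
  manifest <- list(
    patient_id = record$patient_id,
    display_name = record$display_name,
    timezone = record$tz,
    days = data.frame(index = record$days$index,
                      start = fmt_iso(record$days$start),
                      end = fmt_iso(record$days$end)),
    tables = list(continuous = "continuous.csv", episodic = "episodic.csv")
  )
  jsonlite::write_json(manifest, file.path(pdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(pdir)
}

#' Read a patient record from a store
#'
#' @param dir Store root directory.
#' @param patient_id Patient to load; other patients' rows are never touched.
#' @return A [patient_record()].
#' @export
read_store <- function(dir, patient_id) {
  pdir <- file.path(dir, patient_id)
  if (!file.exists(file.path(pdir, "manifest.json"))) {
    stop("patient not found in store: ", patient_id)
  }
  manifest <- jsonlite::read_json(file.path(pdir, "manifest.json"),
                                  simplifyVector = TRUE)
  tz <- manifest$timezone %||% "UTC"
  cont <- utils::read.csv(file.path(pdir, "continuous.csv"),
                          stringsAsFactors = FALSE, colClasses = "character")
  channels <- list()
  if (nrow(cont) > 0L) {
    for (ch in unique(cont$channel)) {
      sub <- cont[cont$channel == ch, , drop = FALSE]
      channels[[ch]] <- channel_series(ch, parse_iso(sub$timestamp, tz = tz),
                                       as.numeric(sub$value))
    }
  }
  epi <- utils::read.csv(file.path(pdir, "episodic.csv"),
                         stringsAsFactors = FALSE, colClasses = "character")
  days <- data.frame(index = as.integer(manifest$days$index),
                     start = parse_iso(manifest$days$start, tz = tz),
                     end = parse_iso(manifest$days$end, tz = tz))
  patient_record(patient_id = manifest$patient_id,
                 display_name = manifest$display_name,
                 channels = channels,
                 episodic = long_to_episodic(epi, tz),
                 days = days, tz = tz)
}

#' List patients present in a store
#'
#' @param dir Store root directory.
#' @return Character vector of patient ids (directories with a manifest).
#' @export
list_patients <- function(dir) {
  if (!dir.exists(dir)) return(character(0))
  cand <- list.dirs(dir, recursive = FALSE, full.names = FALSE)
  cand[file.exists(file.path(dir, cand, "manifest.json"))]
}

#' Read System Usability Scale questionnaires
#'
#' Expects header `respondent_id,item1,...,item10` with integer Likert
#' entries in 1..5; an out-of-range entry is an error naming the respondent
#' and item.
#'
#' @param path CSV file path.
#' @return List of `sus_response` objects (see [score_sus()]).
#' @export
read_sus_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("respondent_id", paste0("item", 1:10))
  if (!all(need %in% names(df))) {
    stop("SUS file must have columns respondent_id,item1..item10")
  }
  lapply(seq_len(nrow(df)), function(i) {
    items <- as.numeric(df[i, paste0("item", 1:10)])
    bad <- which(is.na(items) | items != round(items) | items < 1 | items > 5)
    if (length(bad)) {
      stop(sprintf(
        "respondent %s item%d: Likert entry must be an integer in 1..5",
        df$respondent_id[i], bad[1L]))
    }
    sus_response(df$respondent_id[i], as.integer(items))
  })
}

#' Read a ratings matrix
#'
#' First column is the target id; each remaining column is one rater. All
#' cells must be finite (complete design).
#'
#' @param path CSV file path.
#' @return Numeric matrix, targets in rows, raters in columns, dimnames kept.
#' @export
read_ratings_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 3L) stop("ratings file needs a target column and >= 2 raters")
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1L]])
  if (any(!is.finite(m))) stop("ratings matrix has missing or non-finite cells")
  if (nrow(m) < 2L) stop("ratings matrix needs at least 2 targets")
  m
}
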