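# Single-screen, three-layer SVG rendering. Interactivity in the original
# display (click to move the 8-h band, click a block to open the 30-min view,
# hover cursor) is replaced by an explicit selection_state, so a scene per
# (day, selection) is rendered statically and deterministically.

# Fixed geometry: one iPad-class canvas. Header 10%, Layer 1 20%, Layer 2
# 25%, Layer 3 45% of the height; colors are configurable here because the
# original names colors but not values.
#' @keywords internal
#' @noRd
render_defaults <- function() {
  list(width = 1366, height = 768,
       margin_x = 60,
       frac = c(header = 0.10, layer1 = 0.20, layer2 = 0.25, layer3 = 0.45),
       col_wear = "#1565c0", col_band = "#d32f2f", col_selected = "#d32f2f",
       col_block = "#455a64", col_subjective = "#1565c0",
       col_wave = "#263238", col_threshold = "#d32f2f",
       spo2_range = c(82, 100), hr_range = c(35, 125))
}

#' Construct a selection state
#'
#' The static analog of the display's interaction: which day is open, where
#' the 8-hour band sits on the 24-hour axis, and which 30-minute block of
#' that band is opened in Layer 3 (its Layer-2 blocks turn red).
#'
#' @param day_index Clinical day number.
#' @param window8h_start `POSIXct` start of the 8-h band (within the day).
#' @param block_start `POSIXct` start of the selected block; must lie on the
#'   block grid inside the 8-h band.
#' @return An object of class `selection_state`.
#' @export
selection_state <- function(day_index, window8h_start, block_start) {
  structure(list(day_index = day_index, window8h_start = window8h_start,
                 block_start = block_start),
            class = "selection_state")
}

#' Default selection for a day summary
#'
#' The 8-hour band starts at the sleeping-period start floored to the block
#' grid (clamped so the band fits inside the day); the selected block is the
#' first flagged block inside the band, else the band's first grid block.
#'
#' @param summary A `day_summary` from [summarize_day()].
#' @return A [selection_state()].
#' @export
default_selection <- function(summary) {
  if (is.null(summary$sleep)) {
    stop("day has no sleeping period; pass an explicit selection_state")
  }
  day <- summary$day
  bw <- summary$cfg$block_minutes * 60
  off <- floor(as.numeric(difftime(summary$sleep$start, day$start,
                                   units = "secs")) / bw) * bw
  band_start <- day$start + off
  latest <- day$end - 8 * 3600
  if (band_start > latest) band_start <- latest
  if (band_start < day$start) band_start <- day$start
  band_end <- band_start + 8 * 3600
  in_band <- summary$blocks$start >= band_start & summary$blocks$start < band_end
  block_start <- if (any(in_band)) min(summary$blocks$start[in_band]) else band_start
  selection_state(summary$day_index, band_start, block_start)
}

#' Exact-value cursor readout
#'
#' The vertical cursor of the 30-minute view: for each of the three channels,
#' the value of the sample nearest to `t` within 1 s, else `NA` (a data gap).
#'
#' @param record A [patient_record()].
#' @param t A single `POSIXct` timestamp.
#' @return Named numeric vector `c(spo2 =, heart_rate =, activity =)`.
#' @export
cursor_readout <- function(record, t) {
  out <- c(spo2 = NA_real_, heart_rate = NA_real_, activity = NA_real_)
  for (ch in names(out)) {
    s <- record$channels[[ch]]
    if (is.null(s) || length(s$t) == 0L) next
    s <- sort_series(s)
    d <- abs(as.numeric(s$t) - as.numeric(t))
    i <- which.min(d)
    if (d[i] <= 1) out[ch] <- s$value[i]
  }
  out
}

#' @keywords internal
#' @noRd
check_selection <- function(summary, selection) {
  day <- summary$day
  if (selection$day_index != summary$day_index) {
    stop("selection day_index does not match the summary's day")
  }
  ws <- selection$window8h_start
  if (ws < day$start || ws + 8 * 3600 > day$end) {
    stop("8-h window does not fit inside the day")
  }
  bs <- selection$block_start
  if (bs < ws || bs >= ws + 8 * 3600) {
    stop("selected block outside the 8-h window")
  }
  bw <- summary$cfg$block_minutes * 60
  off <- as.numeric(difftime(bs, day$start, units = "secs"))
  if (abs(off - round(off / bw) * bw) > 1e-6) {
    stop("selected block is not on the block grid")
  }
  invisible(TRUE)
}

#' Build the fully resolved scene for one day
#'
#' Resolves everything the renderer needs into plain geometry and content:
#' the header (patient/day line, every blood-pressure reading with its time,
#' weight and subjective-score entries), Layer 1 (24-h axis, blue wear line
#' if the oximeter was worn, red 8-h band), Layer 2 (violation blocks in
#' three rows ordered SpO2, heart rate, activity over the 8-h window, blocks
#' of the selected 30-min segment marked red), and Layer 3 (three temporally
#' aligned 30-min waveform panels with threshold lines; SpO2 drawn on a fixed
#' 82-100% range, heart rate on 35-125 bpm, values clipped to the range;
#' the activity range auto-scales to keep its threshold visible).
#'
#' @param summary A `day_summary`.
#' @param record The corresponding [patient_record()].
#' @param selection A [selection_state()]; see [default_selection()].
#' @param cfg A [threshold_config()] (defaults to the summary's).
#' @param cursor_t Optional `POSIXct` inside the selected block: draws the
#'   vertical cursor with exact per-channel readouts.
#' @return An object of class `render_scene`.
#' @export
build_scene <- function(summary, record, selection = default_selection(summary),
                        cfg = summary$cfg, cursor_t = NULL) {
  check_selection(summary, selection)
  g <- render_defaults()
  day <- summary$day
  heights <- g$height * g$frac
  y0 <- cumsum(c(0, heights))
  boxes <- list(
    header = c(x = 0, y = y0[[1]], w = g$width, h = heights[[1]]),
    layer1 = c(x = g$margin_x, y = y0[[2]], w = g$width - 2 * g$margin_x,
               h = heights[[2]]),
    layer2 = c(x = g$margin_x, y = y0[[3]], w = g$width - 2 * g$margin_x,
               h = heights[[3]]),
    layer3 = c(x = g$margin_x, y = y0[[4]], w = g$width - 2 * g$margin_x,
               h = heights[[4]])
  )

  bp <- Filter(function(m) m$kind == "blood_pressure", summary$episodic)
  wt <- Filter(function(m) m$kind == "weight", summary$episodic)
  sj <- Filter(function(m) m$kind == "subjective", summary$episodic)
  header <- list(
    title = sprintf("%s - Day %d (%s)", record$display_name, summary$day_index,
                    format(day$start, "%Y-%m-%d")),
    bp = lapply(bp, function(m) list(
      time = format(m$t, "%H:%M"),
      text = sprintf("BP %g/%g mmHg @ %s", m$systolic_mmhg, m$diastolic_mmhg,
                     format(m$t, "%H:%M")))),
    weight = lapply(wt, function(m) list(
      time = format(m$t, "%H:%M"),
      text = sprintf("Weight %g kg @ %s", m$weight_kg, format(m$t, "%H:%M")))),
    subjective = lapply(sj, function(m) list(
      time = format(m$t, "%H:%M"),
      text = sprintf("Score %g @ %s", m$subjective_score, format(m$t, "%H:%M")),
      items = m$subjective_items))
  )

  band_start <- selection$window8h_start
  band_end <- band_start + 8 * 3600
  block_end <- selection$block_start + cfg$block_minutes * 60

  blocks <- summary$blocks
  in_band <- blocks$start < band_end & blocks$end > band_start
  l2 <- blocks[in_band, , drop = FALSE]
  l2$selected <- l2$start >= selection$block_start & l2$end <= block_end

  panels <- lapply(c("spo2", "heart_rate", "activity"), function(ch) {
    s <- day_samples(record, ch, day)
    keep <- s$t >= selection$block_start & s$t < block_end
    t <- s$t[keep]; v <- s$value[keep]
    if (ch == "spo2") {
      rng <- g$spo2_range; thr <- cfg$spo2_low
    } else if (ch == "heart_rate") {
      rng <- g$hr_range; thr <- c(cfg$hr_low, cfg$hr_high)
    } else {
      top <- max(2 * cfg$activity_high, if (length(v)) max(v) else 0)
      rng <- c(0, top); thr <- cfg$activity_high
    }
    list(channel = ch, t = t, value = pmin(pmax(v, rng[1]), rng[2]),
         range = rng, thresholds = thr)
  })
  names(panels) <- c("spo2", "heart_rate", "activity")

  cursor <- NULL
  if (!is.null(cursor_t)) {
    if (cursor_t < selection$block_start || cursor_t >= block_end) {
      stop("cursor_t outside the selected block")
    }
    cursor <- list(t = cursor_t, readout = cursor_readout(record, cursor_t))
  }

  structure(
    list(geometry = list(width = g$width, height = g$height, boxes = boxes,
                         colors = g),
         header = header,
         layer1 = list(day_start = day$start, day_end = day$end,
                       wear = summary$wear$intervals,
                       band = list(start = band_start, end = band_end)),
         layer2 = list(window_start = band_start, window_end = band_end,
                       blocks = l2,
                       selected = list(start = selection$block_start,
                                       end = block_end)),
         layer3 = list(window_start = selection$block_start, window_end = block_end,
                       panels = panels, cursor = cursor),
         selection = selection,
         day_index = summary$day_index),
    class = "render_scene"
  )
}

# Deterministic number formatting: fixed 2 decimals everywhere so identical
# scenes give byte-identical SVG.
#' @keywords internal
#' @noRd
fx <- function(x) sprintf("%.2f", x)

#' @keywords internal
#' @noRd
xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Render a scene to SVG text
#'
#' Pure function of the scene: identical scenes give byte-identical SVG (no
#' timestamps, no randomness). Waveforms are `<polyline>` paths; element ids
#' are stable and queryable (`layer1`, `layer1.wear`, `layer2.row_spo2`,
#' `layer2.row_spo2.block_<i>`, `layer3.panel_heart_rate`, ...). Flagged
#' blocks carry class `violation-block`, the selected segment's blocks
#' additionally `selected` and the red fill. An empty day renders axes and
#' "no data" placeholders.
#'
#' @param scene A `render_scene` from [build_scene()].
#' @param path Optional file to write; the SVG text is returned invisibly
#'   then.
#' @return SVG document text (a single character string).
#' @export
render_svg <- function(scene, path = NULL) {
  g <- scene$geometry
  col <- g$colors
  out <- character(0)
  add <- function(...) out <<- c(out, sprintf(...))

  add('<?xml version="1.0" encoding="UTF-8"?>')
  add('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d" font-family="Helvetica, Arial, sans-serif">',
      g$width, g$height, g$width, g$height)
  add('<rect x="0" y="0" width="%d" height="%d" fill="#ffffff"/>',
      g$width, g$height)

  # ---- header --------------------------------------------------------------
  hb <- g$boxes$header
  add('<g id="header">')
  add('<text x="%s" y="%s" font-size="18" font-weight="bold">%s</text>',
      fx(hb["x"] + 12), fx(hb["y"] + 22), xml_escape(scene$header$title))
  hx <- hb["x"] + 12
  for (i in seq_along(scene$header$bp)) {
    add('<text id="header.bp_%d" x="%s" y="%s" font-size="13">%s</text>',
        i, fx(hx), fx(hb["y"] + 42), xml_escape(scene$header$bp[[i]]$text))
    hx <- hx + 220
  }
  hx <- hb["x"] + 12
  for (i in seq_along(scene$header$weight)) {
    add('<text id="header.weight_%d" x="%s" y="%s" font-size="13">%s</text>',
        i, fx(hx), fx(hb["y"] + 60), xml_escape(scene$header$weight[[i]]$text))
    hx <- hx + 220
  }
  for (i in seq_along(scene$header$subjective)) {
    sj <- scene$header$subjective[[i]]
    add('<g id="header.subjective_%d"><rect x="%s" y="%s" width="110" height="16" fill="%s" opacity="0.85"/><text x="%s" y="%s" font-size="12" fill="#ffffff">%s</text></g>',
        i, fx(hx), fx(hb["y"] + 48), col$col_subjective,
        fx(hx + 4), fx(hb["y"] + 60), xml_escape(sj$text))
    hx <- hx + 130
  }
  add('</g>')

  # ---- layer 1: 24-h overview ---------------------------------------------
  b1 <- g$boxes$layer1
  t0 <- as.numeric(scene$layer1$day_start)
  t1 <- as.numeric(scene$layer1$day_end)
  x_of <- function(t, tmin, tmax, box) {
    box[["x"]] + (as.numeric(t) - tmin) / (tmax - tmin) * box[["w"]]
  }
  axis_y <- b1["y"] + b1["h"] * 0.55
  add('<g id="layer1">')
  add('<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="#000000" stroke-width="1"/>',
      fx(b1["x"]), fx(axis_y), fx(b1["x"] + b1["w"]), fx(axis_y))
  for (h in seq(0, 24, by = 2)) {
    xt <- b1["x"] + b1["w"] * h / 24
    add('<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="#000000" stroke-width="1"/>',
        fx(xt), fx(axis_y), fx(xt), fx(axis_y + 5))
    lab <- format(scene$layer1$day_start + h * 3600, "%H:%M")
    add('<text x="%s" y="%s" font-size="10" text-anchor="middle">%s</text>',
        fx(xt), fx(axis_y + 18), lab)
  }
  wear <- scene$layer1$wear
  if (nrow(wear) > 0L) {
    add('<g id="layer1.wear">')
    for (i in seq_len(nrow(wear))) {
      add('<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="5" stroke-linecap="round"/>',
          fx(x_of(wear$start[i], t0, t1, b1)), fx(axis_y - 12),
          fx(x_of(wear$end[i], t0, t1, b1)), fx(axis_y - 12), col$col_wear)
    }
    add('</g>')
  }
  band <- scene$layer1$band
  add('<rect id="layer1.band" x="%s" y="%s" width="%s" height="%s" fill="%s" opacity="0.25" stroke="%s"/>',
      fx(x_of(band$start, t0, t1, b1)), fx(b1["y"] + b1["h"] * 0.15),
      fx((as.numeric(band$end) - as.numeric(band$start)) / (t1 - t0) * b1["w"]),
      fx(b1["h"] * 0.6),
      col$col_band, col$col_band)
  add('</g>')

  # ---- layer 2: 8-h violation blocks --------------------------------------
  b2 <- g$boxes$layer2
  w0 <- as.numeric(scene$layer2$window_start)
  w1 <- as.numeric(scene$layer2$window_end)
  rows <- c("spo2", "heart_rate", "activity")
  row_h <- b2["h"] / 3.6
  add('<g id="layer2">')
  blocks <- scene$layer2$blocks
  for (r in seq_along(rows)) {
    ch <- rows[r]
    ry <- b2["y"] + (r - 1) * row_h * 1.15 + 8
    add('<g id="layer2.row_%s">', ch)
    add('<text x="%s" y="%s" font-size="11" text-anchor="end">%s</text>',
        fx(b2["x"] - 6), fx(ry + row_h * 0.65),
        c(spo2 = "SaO2", heart_rate = "HR", activity = "Act")[[ch]])
    add('<rect x="%s" y="%s" width="%s" height="%s" fill="none" stroke="#9e9e9e" stroke-width="0.5"/>',
        fx(b2["x"]), fx(ry), fx(b2["w"]), fx(row_h))
    sel <- blocks$channel == ch
    if (any(sel)) {
      sub <- blocks[sel, , drop = FALSE]
      for (i in seq_len(nrow(sub))) {
        xs <- max(as.numeric(sub$start[i]), w0)
        xe <- min(as.numeric(sub$end[i]), w1)
        fill <- if (sub$selected[i]) col$col_selected else col$col_block
        cls <- if (sub$selected[i]) "violation-block selected" else "violation-block"
        add('<rect id="layer2.row_%s.block_%d" class="%s" x="%s" y="%s" width="%s" height="%s" fill="%s"><title>%s %s %s</title></rect>',
            ch, i, cls,
            fx(b2["x"] + (xs - w0) / (w1 - w0) * b2["w"]), fx(ry + 2),
            fx((xe - xs) / (w1 - w0) * b2["w"]), fx(row_h - 4), fill,
            ch, sub$kind[i], fx(sub$statistic[i]))
      }
    }
    add('</g>')
  }
  if (nrow(blocks) == 0L) {
    add('<text id="layer2.empty" x="%s" y="%s" font-size="12" text-anchor="middle" fill="#757575">no threshold violations</text>',
        fx(b2["x"] + b2["w"] / 2), fx(b2["y"] + b2["h"] / 2))
  }
  add('</g>')

  # ---- layer 3: 30-min aligned waveforms ----------------------------------
  b3 <- g$boxes$layer3
  s0 <- as.numeric(scene$layer3$window_start)
  s1 <- as.numeric(scene$layer3$window_end)
  panel_h <- b3["h"] / 3.2
  add('<g id="layer3">')
  for (r in seq_along(rows)) {
    ch <- rows[r]
    p <- scene$layer3$panels[[ch]]
    py <- b3["y"] + (r - 1) * panel_h * 1.06 + 6
    y_of <- function(v) py + panel_h - (v - p$range[1]) / diff(p$range) * panel_h
    add('<g id="layer3.panel_%s">', ch)
    add('<rect x="%s" y="%s" width="%s" height="%s" fill="none" stroke="#9e9e9e" stroke-width="0.5"/>',
        fx(b3["x"]), fx(py), fx(b3["w"]), fx(panel_h))
    add('<text x="%s" y="%s" font-size="11" text-anchor="end">%s</text>',
        fx(b3["x"] - 6), fx(py + panel_h / 2),
        c(spo2 = "SaO2 %", heart_rate = "HR bpm", activity = "Act vmu")[[ch]])
    add('<text x="%s" y="%s" font-size="9" text-anchor="start">%s</text>',
        fx(b3["x"] + b3["w"] + 4), fx(py + 8), fx(p$range[2]))
    add('<text x="%s" y="%s" font-size="9" text-anchor="start">%s</text>',
        fx(b3["x"] + b3["w"] + 4), fx(py + panel_h), fx(p$range[1]))
    for (thr in p$thresholds) {
      add('<line class="threshold" x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="0.8" stroke-dasharray="4 3"/>',
          fx(b3["x"]), fx(y_of(thr)), fx(b3["x"] + b3["w"]), fx(y_of(thr)),
          col$col_threshold)
    }
    if (length(p$t) > 0L) {
      pts <- paste(
        fx(b3["x"] + (as.numeric(p$t) - s0) / (s1 - s0) * b3["w"]),
        fx(y_of(p$value)),
        sep = ",", collapse = " ")
      add('<polyline id="layer3.wave_%s" points="%s" fill="none" stroke="%s" stroke-width="1"/>',
          ch, pts, col$col_wave)
    } else {
      add('<text id="layer3.panel_%s.empty" x="%s" y="%s" font-size="12" text-anchor="middle" fill="#757575">no data</text>',
          ch, fx(b3["x"] + b3["w"] / 2), fx(py + panel_h / 2))
    }
    add('</g>')
  }
  cur <- scene$layer3$cursor
  if (!is.null(cur)) {
    cx <- b3["x"] + (as.numeric(cur$t) - s0) / (s1 - s0) * b3["w"]
    add('<g id="layer3.cursor">')
    add('<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="#000000" stroke-width="1" stroke-dasharray="2 2"/>',
        fx(cx), fx(b3["y"]), fx(cx), fx(b3["y"] + b3["h"]))
    lab <- paste(
      sprintf("%s=%s",
              c("SaO2", "HR", "Act"),
              ifelse(is.na(cur$readout), "-", fx(cur$readout))),
      collapse = " ")
    add('<text x="%s" y="%s" font-size="10">%s</text>',
        fx(cx + 4), fx(b3["y"] + 12), lab)
    add('</g>')
  }
  add('</g>')
  add('</svg>')

  txt <- paste(out, collapse = "\n")
  if (is.null(path)) return(txt)
  writeLines(txt, path, useBytes = TRUE)
  invisible(txt)
}

#' Dump a scene as JSON for golden-file testing
#'
#' @param scene A `render_scene`.
#' @param path Optional output file.
#' @return JSON text (invisibly when written).
#' @export
scene_json <- function(scene, path = NULL) {
  simplify_t <- function(x) {
    if (inherits(x, "POSIXct")) return(fmt_iso(x))
    if (is.data.frame(x)) {
      for (nm in names(x)) if (inherits(x[[nm]], "POSIXct")) x[[nm]] <- fmt_iso(x[[nm]])
      return(x)
    }
    if (is.list(x)) return(lapply(x, simplify_t))
    x
  }
  obj <- simplify_t(unclass(scene))
  obj$geometry$colors <- NULL
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}
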