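# A small scene fixture: one night with a desaturation, an HR spike, two BP
# readings, a weight and a subjective entry.
make_scene_fixture <- function(with_wear = TRUE, with_bp = 2L) {
  v <- rep(96, 7 * 3600); v[3600 + 1:300] <- 88; v[300:310] <- 80
  spo2 <- channel_series("spo2", utc("2016-01-04 23:00:00") + seq_along(v) - 1, v)
  hv <- rep(80, 7 * 3600); hv[2 * 3600 + 1:200] <- 110
  hr <- channel_series("heart_rate", utc("2016-01-04 23:00:00") + seq_along(hv) - 1, hv)
  channels <- if (with_wear) list(spo2, hr) else list(hr)
  epi <- c(
    lapply(seq_len(with_bp), function(i) episodic_measurement(
      "blood_pressure", utc("2016-01-04 18:00:00") + (i - 1) * 3600 * 10,
      systolic_mmhg = 120 + i, diastolic_mmhg = 75)),
    list(episodic_measurement("weight", utc("2016-01-05 07:30:00"),
                              weight_kg = 82.5),
         episodic_measurement("subjective", utc("2016-01-04 21:00:00"),
                              subjective_score = 6,
                              subjective_items = c(fatigue = 7, mood = 5))))
  r <- make_record(channels, episodic = epi)
  s <- summarize_day(r, 1)
  list(record = r, summary = s)
}

test_that("build_scene resolves header, wear, blocks and clipping", {
  fx <- make_scene_fixture()
  scene <- build_scene(fx$summary, fx$record)
  expect_length(scene$header$bp, 2L) # both BP readings with times
  expect_length(scene$header$weight, 1L)
  expect_length(scene$header$subjective, 1L)
  expect_gt(nrow(scene$layer1$wear), 0L)
  # every flagged block in the band appears exactly once in layer 2
  expect_equal(nrow(scene$layer2$blocks), nrow(fx$summary$blocks))
  # SpO2 values below the display floor are clipped to 82
  expect_true(all(scene$layer3$panels$spo2$value >= 82))
  expect_true(any(fx$record$channels$spo2$value < 82))

  # no pulse-ox wear -> no wear intervals in the scene
  fx2 <- make_scene_fixture(with_wear = FALSE)
  scene2 <- build_scene(fx2$summary, fx2$record)
  expect_equal(nrow(scene2$layer1$wear), 0L)
  expect_false(grepl("layer1.wear", render_svg(scene2), fixed = TRUE))
})

test_that("render_svg is deterministic, well-formed, and styles selection", {
  fx <- make_scene_fixture()
  scene <- build_scene(fx$summary, fx$record)
  svg1 <- render_svg(scene)
  svg2 <- render_svg(build_scene(fx$summary, fx$record))
  expect_identical(svg1, svg2) # byte-identical on identical scenes

  doc <- xml2::read_xml(svg1) # throws if not well-formed XML
  expect_equal(xml2::xml_name(doc), "svg")

  # exactly the flagged blocks drawn; exactly the selected segment red
  ns <- xml2::xml_ns(doc)
  blocks <- xml2::xml_find_all(doc, "//d1:rect[contains(@class,'violation-block')]",
                               ns = ns)
  expect_length(blocks, nrow(scene$layer2$blocks))
  selected <- xml2::xml_find_all(doc, "//d1:rect[contains(@class,'selected')]",
                                 ns = ns)
  expect_length(selected, sum(scene$layer2$blocks$selected))
  expect_gte(length(selected), 1L)
  # selected blocks all lie in the selected 30-min segment
  expect_true(all(scene$layer2$blocks$selected ==
                    (scene$layer2$blocks$start >= scene$layer2$selected$start &
                       scene$layer2$blocks$end <= scene$layer2$selected$end)))
})

test_that("layer-3 panels share one time axis (x of equal timestamps equal)", {
  fx <- make_scene_fixture()
  scene <- build_scene(fx$summary, fx$record)
  svg <- render_svg(scene)
  doc <- xml2::read_xml(svg)
  ns <- xml2::xml_ns(doc)
  waves <- xml2::xml_find_all(doc, "//d1:polyline", ns = ns)
  expect_gte(length(waves), 2L)
  xs <- lapply(waves, function(w) {
    pts <- strsplit(xml2::xml_attr(w, "points"), " ")[[1]]
    vapply(strsplit(pts, ","), function(p) as.numeric(p[1]), numeric(1))
  })
  # both panels cover the same 30-min window at 1 Hz: identical x vectors
  expect_equal(xs[[1]], xs[[2]])
})

test_that("an empty day still renders a valid placeholder SVG", {
  r <- make_record(list(make_series("spo2", "2016-01-04 23:00:00", 10, 96)),
                   n_days = 2L)
  s2 <- summarize_day(r, 2)
  expect_error(default_selection(s2), "explicit selection")
  sel <- selection_state(2L, r$days$start[2], r$days$start[2])
  svg <- render_svg(build_scene(s2, r, sel))
  expect_no_error(xml2::read_xml(svg))
  expect_match(svg, "no data")
  expect_match(svg, "no threshold violations")
})

test_that("default_selection floors the band to the grid and picks first flag", {
  fx <- make_scene_fixture()
  sel <- default_selection(fx$summary)
  expect_equal(sel$window8h_start, fx$summary$sleep$start) # already on grid
  expect_equal(sel$block_start, min(fx$summary$blocks$start))

  # no flags -> first grid block of the band
  r <- make_record(list(make_series("spo2", "2016-01-04 23:07:00", 3600, 96)))
  s <- summarize_day(r, 1)
  sel2 <- default_selection(s)
  expect_equal(sel2$window8h_start, utc("2016-01-04 23:00:00"))
  expect_equal(sel2$block_start, utc("2016-01-04 23:00:00"))

  # late sleep onset: 8-h band clamps inside the day
  r3 <- make_record(list(make_series("spo2", "2016-01-05 11:00:00", 3600, 96)))
  s3 <- summarize_day(r3, 1)
  sel3 <- default_selection(s3)
  expect_equal(sel3$window8h_start + 8 * 3600, r3$days$end[1])
})

test_that("selection validation rejects out-of-day and off-grid choices", {
  fx <- make_scene_fixture()
  day <- fx$summary$day
  expect_error(build_scene(fx$summary, fx$record,
                           selection_state(1L, day$start - 3600, day$start)),
               "does not fit")
  expect_error(build_scene(fx$summary, fx$record,
                           selection_state(1L, day$start, day$start + 123)),
               "not on the block grid")
  expect_error(build_scene(fx$summary, fx$record,
                           selection_state(2L, day$start, day$start)),
               "day_index")
})

test_that("cursor readout is nearest-within-1s per channel", {
  t0 <- utc("2016-01-05 02:00:00")
  spo2 <- channel_series("spo2", t0 + c(0, 10), c(95, 93))
  hr <- channel_series("heart_rate", t0 + c(0.3, 0.7), c(70, 72))
  r <- make_record(list(spo2, hr))
  # exactly on a sample: unmodified value
  expect_equal(cursor_readout(r, t0)[["spo2"]], 95)
  # in a gap: NA for that channel
  expect_true(is.na(cursor_readout(r, t0 + 5)[["spo2"]]))
  # between two samples 0.4 s apart: the nearer one wins
  expect_equal(cursor_readout(r, t0 + 0.45)[["heart_rate"]], 70)
  expect_equal(cursor_readout(r, t0 + 0.55)[["heart_rate"]], 72)
  # channel with no samples at all
  expect_true(is.na(cursor_readout(r, t0)[["activity"]]))
})
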