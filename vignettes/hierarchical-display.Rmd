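---
title: "Methods: a three-layer temporal display of nocturnal home-monitoring physiology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a three-layer temporal display of nocturnal home-monitoring physiology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(noctview)
```

## The problem and the model of the data

Outpatients with heart failure collect nocturnal physiology at home with
consumer-grade devices: a pulse oximeter (SpO2, %), which also reports pulse
rate (bpm), and a wrist actigraph (activity in vector magnitude units, VMU),
all at a nominal 1 Hz; plus episodic entries — body weight, blood-pressure
readings and subjective-state question sets — once or a few times per day.
The package's data model mirrors this split exactly: `channel_series` for
the three continuous channels, `episodic_measurement` for the rest, both
stored (and persisted) in separate per-patient tables because the two kinds
of data have different shapes, volumes and access patterns.

Time is organised into **clinical days**: 24-h windows from 16:00 local
time to 16:00 the next day, so that one full night of monitoring falls
inside one window. Windows are half-open `[start, end)` — a datum at
exactly 16:00 belongs to the day beginning then — which avoids double
counting at boundaries. Day 1 anchors at the most recent 16:00 at or before
the earliest datum. Windows are fixed 86 400-s spans from that anchor; under
a daylight-saving transition later windows therefore drift off 16:00 local.
We chose the fixed-span reading (contiguity and constant length) over
re-anchoring each day at local 16:00, which would create 23/25-h days; the
test fixtures use UTC, where the two readings coincide.

## Detection

**Sleeping period.** The devices are worn only in bed, so presence of SpO2
or heart-rate data marks the monitored night: the sleeping period runs from
the start of the first 30-min slot containing any SpO2/HR sample to the end
of the last such slot in the day. The slot width equals the violation-block
grid (a parameter, default 30 min), and the grid is anchored at the 16:00
day start rather than at sleep onset, so block boundaries are stable and
comparable across days. Absence of data is a valid outcome (`NULL`), not an
error.

**Wear.** Pulse-oximeter wear is the set of maximal intervals in which
consecutive SpO2 samples are at most 60 s apart (`gap_tolerance`). This is
what the display's blue line shows; no SpO2 data, no line.

**Violation blocks.** Each 30-min grid interval is tested per channel:

| channel | rule | statistic |
|---|---|---|
| SpO2 | any sample < 92 % | block minimum |
| heart rate | any sample < 60 bpm (low); any sample > 100 bpm (high) | block min / max |
| activity | block **mean** > 12 VMU | block mean |

The activity rule is the only one defined as an average ("real activity");
for SpO2/HR the per-block semantics were open and we chose any-sample
crossing — the most sensitive reading — with a configurable
`min_violation_samples` filter (default 1) for users who want a minimum
violation duration. All inequalities are strict: a block sitting exactly at
92 / 60 / 100 / 12 never flags (unit-tested at the boundary). Blocks with
zero samples are absent, never flagged. One heart-rate block may yield both
a low and a high flag. `summarize_day()` restricts flags to grid intervals
overlapping the sleeping period, because the 8-h layer shows
sleeping-period detail: a daytime activity bout is deliberately not
reported.

## Rendering

A scene is a pure function of `(day summary, record, selection,
thresholds)`; SVG text is a pure function of the scene, with fixed 2-decimal
coordinate formatting, so identical scenes give byte-identical files. The
original system's interactions (moving the 8-h band, clicking a block,
hovering a cursor) become parameters of `selection_state`, making every
display state reproducible and testable. Geometry is a 1366×768 canvas
split 10 % header / 20 % / 25 % / 45 % for the three layers; colors (wear
line `#1565c0`, band and selected blocks `#d32f2f`) are package choices —
the display concept names colors, not values. Display ranges are fixed at
82–100 % (SpO2) and 35–125 bpm (HR), with samples clipped to the range;
activity has no published display range, so its panel auto-scales to
`[0, max(2 × threshold, observed max)]` to keep the threshold line visible.
The default selection floors the sleep start to the grid for the 8-h band
(clamped inside the day) and opens the band's first flagged block, else its
first grid block.

## The synthetic generator: what it does and does not emulate

The generator exists so that every detection and rendering path is testable
without patient data. Signals are piecewise-constant baselines plus Gaussian
per-sample jitter plus trapezoidal event excursions (15 % ramps); there is
no cardiopulmonary model, no sleep staging, no medication effects. Defaults
state a plausible six-night heart-failure world, chosen once:

* sleep onset ~N(23:00, 30 min), duration ~N(7 h, 0.75 h);
* SpO2 baseline 96 % (jitter SD 0.5 — 8 SD above the 92 % threshold, so
  baseline noise essentially never flags), 3 desaturations/night to
  85–91 % for 60–300 s;
* HR baseline 72 bpm (SD 2), one bradycardia (45–58 bpm) and one
  tachycardia (102–115 bpm) episode per night, 60–300 s;
* 2 nocturnal out-of-bed bouts per night, 5–25 min at 20–60 VMU — chosen so
  that 30-min block means straddle the 12-VMU threshold, i.e. both flagged
  and unflagged bouts occur;
* 2 % Bernoulli sample dropout plus an occasional 2–15-min gap (exercises
  wear splitting); weight drifting +0.3 kg/day (fluid retention), two BP
  readings and one evening subjective entry per day.

The **ground-truth expected block set** is computed by an independent naive
per-sample scan over the *final* generated samples (after jitter, clipping
and dropout), not from event geometry: with ramps plus jitter, geometry
alone cannot decide borderline blocks. The scan shares no code with the
detection module, and the test suite carries a third, separately written
brute-force oracle. A green detection-recovery test therefore establishes
that the vectorized detection path agrees exactly with a transparent
sample-by-sample reading of the rules on realistic signals — it does not
establish anything about real device artifacts (motion corruption, oximeter
dropout bias, pre-epoched actigraphy), which the generator does not model.

The SUS questionnaire generator targets a sample mean/SD of transformed
scores: draws are standardized to the target, snapped to the 2.5-point SUS
grid, clipped to [0, 100] and refined by a deterministic hill-climb until
the sample mean is within 0.15 and the SD within 0.2 of target (the
contract is ±1 point; the tighter internal tolerance keeps derived
confidence intervals stable at n = 14). Infeasible targets (boundary mean
with positive SD, SD beyond the [0, 100] population bound) error.

## Usability statistics

SUS items are 1–5 Likert; odd items contribute `rating − 1`, even items
`5 − rating`; overall = 2.5 × total. The Lewis–Sauro subscales weight items
4 and 8 by 12.5 (learnability) and the remaining eight by 3.125
(usability), which makes `overall = 0.8·usability + 0.2·learnability` an
exact identity — property-tested over random responses, and the resolution
of an internally inconsistent worked example we encountered while
specifying the scorer (all items 5 gives overall 50, usability 62.5,
learnability 0).

The benchmark test is a one-sample two-sided t against the literature
"highly acceptable" anchor of 68. The anchor's published SD (12.5) is *not*
used: a one-sample t uses the sample SD (with mean 92, SD 9, n 14 both
choices give p < 0.0001, so the ambiguity is immaterial here). CIs are the
standard two-sided `mean ± t(1−α/2, n−1)·sd/√n`, reported at full precision
with an optional nearest-integer display rounding that reproduces printed
tables. Reproducing the published summary table from its printed mean/SD/n
recovers (87, 97) for 92 ± 9 and (86, 98) for 92 ± 10; for 93 ± 10 the
exact interval is (87.23, 98.77), whose upper bound rounds to 99, not the
printed 98 — we report the discrepancy rather than adjust anything.

ICC(3,1) — two-way mixed, consistency, single measures — is
`(BMS − EMS)/(BMS + (k−1)·EMS)` from the two-way ANOVA decomposition, with
the exact F-bound confidence interval
(`FL = F/F₁₋α/₂(n−1,(n−1)(k−1))`, `FU = F·F₁₋α/₂((n−1)(k−1),n−1)`, each
mapped through `(x−1)/(x+k−1)`) and the p-value from `F ~ F(n−1,
(n−1)(k−1))` under ICC = 0. Degenerate inputs: a perfectly additive matrix
(zero residual) returns ICC exactly 1 with a degenerate CI; a constant
matrix errors. Being a consistency ICC it is invariant to per-rater column
shifts, which is property-tested, as is equality with a from-scratch
double-loop ANOVA oracle to 1e-10.

## Numerical and design choices

* Duplicate `(channel, timestamp)` rows on ingestion are averaged with a
  warning — device re-transmission should not abort a night's upload.
* Constructors preserve sample order so the validator can name the first
  inversion; analysis functions sort defensively, making detection
  order-invariant.
* Timestamps serialize as ISO-8601 with offset; store round-trips are exact
  to 1 s and to the stored decimal precision of values.
* The storage backend is CSV-per-table plus a JSON manifest — desk-scale
  and dependency-free — but keeps the two-table episodic/continuous split,
  which is the design worth preserving from the original system.
* The boundary hour (16) is a parameter rather than a hard-coded constant,
  since real deployments may roll days at a different hour.

## Known limitations

* No artifact rejection or smoothing of raw signals; no apnea/arrhythmia
  scoring beyond the three threshold rules.
* Activity handling assumes per-second VMU values averaged over blocks;
  devices that pre-epoch activity need resampling upstream.
* Day windows under DST drift (see above).
* The renderer is static; there is no browser front end, zoom/pan, or EHR
  integration.
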