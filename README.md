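# noctview

Heart-failure patients experience many of their serious symptoms at home, at
night, and usually cannot recall them at the next clinic visit. Mobile
devices (a pulse oximeter, an actigraph, a blood-pressure cuff, a scale and a
tablet for subjective-state questions) let patients collect that information
themselves — but a week of 1 Hz physiology is far too much to read linearly
during a visit. `noctview` implements the reviewing side of such a
home-monitoring workflow for clinicians and for informatics researchers
studying clinical displays:

* **Clinical-day partitioning** — raw timestamped data are split into 24-h
  windows running 4 pm → 4 pm local time, so a full night lies inside one
  window.
* **Detection** — the sleeping period of a day is the span from the first to
  the last 30-min slot containing any SpO2 or heart-rate sample;
  pulse-oximeter *wear* is the set of maximal SpO2 runs with gaps ≤ 60 s; and
  each 30-min grid block is checked against the thresholds
  SpO2 < 92 %, HR < 60 or > 100 bpm, and 30-min **mean** activity > 12
  vector magnitude units ("real activity"). All comparisons are strict.
* **Rendering** — one deterministic SVG screen per day with three stacked
  temporal layers: a 24-h overview (wear line, red 8-h band, episodic
  weight/BP/subjective entries in the header), an 8-h band of violation
  blocks in three rows (SaO2, HR, activity), and a 30-min second-level
  waveform view (SpO2 displayed on 82–100 %, HR on 35–125 bpm) with
  temporally aligned panels and an optional exact-value cursor. Interaction
  is replaced by an explicit `selection_state`, so rendering is a pure,
  testable function.
* **Synthetic data** — a seeded six-night generator with desaturations,
  brady/tachycardia episodes, nocturnal activity bouts, dropout gaps and
  daily episodic entries, plus a ground-truth log of the grid blocks that
  must flag.
* **Usability statistics** — System Usability Scale scoring
  (`overall = 2.5 × Σ contributions`, Lewis–Sauro subscales:
  learnability = items 4 & 8 × 12.5, usability = the other eight × 3.125,
  so `overall = 0.8·usability + 0.2·learnability` exactly), a one-sample
  t-test against the literature benchmark 68, and the intraclass
  correlation ICC(3,1) = (BMS − EMS)/(BMS + (k−1)·EMS) with exact
  Shrout–Fleiss F-based confidence bounds.

## Worked example

```r
library(noctview)

gen <- generate_record(generator_config(seed = 42))
r   <- gen$record
s   <- summarize_day(r, 1)
s
#> <day_summary> day 1: sleep 23:30 - 06:30, 2 wear interval(s), 7 violation block(s), 4 episodic
s$blocks
#>      channel kind               start                 end statistic n_samples
#> 1       spo2  low 2016-01-04 23:30:00 2016-01-05 00:00:00  89.40000      1113
#> 2       spo2  low 2016-01-05 01:30:00 2016-01-05 02:00:00  88.10000      1531
#> 3       spo2  low 2016-01-05 05:00:00 2016-01-05 05:30:00  89.10000      1763
#> 4 heart_rate  low 2016-01-05 01:00:00 2016-01-05 01:30:00  45.60000      1757
#> 5 heart_rate high 2016-01-05 04:00:00 2016-01-05 04:30:00 114.70000      1758
#> 6   activity high 2016-01-05 03:30:00 2016-01-05 04:00:00  13.89034      1757
#> 7   activity high 2016-01-05 04:00:00 2016-01-05 04:30:00  13.04860      1773

render_svg(build_scene(s, r, default_selection(s)), "day1.svg")
```

The summary says: on night 1 the patient slept (i.e. wore the oximeter) from
the 23:30 slot through the 06:30 slot with one gap in wear; three 30-min
blocks contained SpO2 samples below 92 % (block minima 89.4/88.1/89.1 %),
one block dipped below 60 bpm (minimum 45.6), one exceeded 100 bpm (maximum
114.7), and two blocks crossed the real-activity bar with 30-min mean
activity 13.9 and 13.0 VMU. The SVG shows those seven blocks in Layer 2; the first
(23:30 SpO2) is selected and drawn red, and its 30 min of raw waveforms fill
Layer 3.

Usability statistics from questionnaire summaries:

```r
tr <- sus_ttest_summary(mean = 92, sd = 9, n = 14, benchmark = 68)
round(c(tr$ci_low, tr$ci_high))   # 87 97
tr$p_value                        # 1.846332e-07
```

## Command line

```
Rscript inst/cli/noctview simulate --seed 42 --out store/
Rscript inst/cli/noctview detect   --store store/ --patient synthetic-001 --out summaries.json
Rscript inst/cli/noctview render   --store store/ --patient synthetic-001 --day 1 --out day1.svg
Rscript inst/cli/noctview sus      --sus sus.csv --ratings ratings.csv --out table.csv
```

Threshold flags (`--spo2-low`, `--hr-low`, `--hr-high`, `--activity-high`,
`--block-minutes`) apply to `detect` and `render`.

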