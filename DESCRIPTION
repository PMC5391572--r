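Package: noctview
Title: Hierarchical Single-Screen Display of Nocturnal Home-Monitoring
    Physiology
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for reviewing multi-night, patient-collected nocturnal
    physiology (pulse-oximetry SpO2, heart rate, actigraph activity, plus
    episodic weight, blood pressure and subjective-state entries).
    Partitions raw timestamped data into 4 pm-to-4 pm clinical days,
    detects sleep and device-wear periods, flags 30-minute
    threshold-violation blocks per channel, and renders a deterministic
    single-screen, three-layer (24 h / 8 h / 30 min) focus-plus-context
    SVG display. Includes a seeded synthetic six-night record generator
    with a ground-truth event log, System Usability Scale scoring with
    the Lewis-Sauro usability and learnability subscales, a one-sample
    benchmark t-test, and the intraclass correlation ICC(3,1) with exact
    F-based confidence intervals. A small command-line interface wires
    the pipeline together.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
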