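Package: CircaScreen
Title: Plate-Based Circadian Reverse-Genetic Screen Analysis for
    Bioluminescence Reporters
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing luciferase-based circadian screens of
    knockout collections. Implements FFT-seeded nonlinear least-squares
    (FFT-NLLS) cosine fitting to estimate free-running periods from
    plate-based bioluminescence time series, relative amplitude error (RAE)
    rhythmicity classification, per-strain period change (delta-tau) against
    per-run wild-type internal controls, 3-SD wild-type tolerance-interval
    hit calling on progeny medians, and dual-reporter confirmation of hits.
    Includes a synthetic plate-screen generator with known ground truth so
    the whole pipeline can be validated by parameter-recovery and
    null-screen experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    minpack.lm,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: TimeCourse, CircadianRhythms, Regression, QualityControl
RoxygenNote: 7.3.3
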