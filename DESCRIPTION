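Package: mcgtools
Title: Mechanocardiogram Analysis of Cardiomyocyte Contraction Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for force-time recordings
    (mechanocardiograms) of spontaneously beating cardiomyocyte clusters,
    as acquired with an atomic force microscope cantilever resting on an
    embryoid body. Detects contraction events (R and S peaks) in
    drift-contaminated traces, derives contraction forces, beat rates and
    interbeat (RR) intervals, scores beat-rate variability (SDSD and
    Poincare SD1/SD2 with median-based RR artifact filtering), counts
    long-pause arrhythmic events against a 3 second cut-off with a
    Yates-corrected chi-square group test, and computes baseline-normalised
    dose-response statistics (relative responses, log-concentration slope
    with Wald test, Holm-Sidak / Games-Howell / Dunn multiple comparisons).
    Includes a seeded synthetic trace generator with ground-truth
    annotations so every stage can be validated without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
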