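Package: pupilfatigue
Title: Objective Visual Fatigue Measurement from Infrared Pupillometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Measures visual fatigue objectively from infrared eye-image
    recordings. Binary pupil-candidate masks (from a pluggable segmentation
    backend, with a classical dark-pupil intensity-threshold baseline) are
    post-processed by contour detection, aspect-ratio and area filtering,
    largest-candidate selection and least-squares ellipse fitting to build a
    per-frame pupil-size time series (0 where no pupil is visible). From the
    series the package extracts three fatigue features: pupil accommodation
    speed via inflection-point detection, blink frequency from maximal
    zero-runs, and eye-closed duration; features are compared between viewing
    conditions with two-sample significance tests. A seeded synthetic-data
    generator produces ground-truth-annotated pupil signals and rendered
    infrared-style eye frames so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    tiff,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
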