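Package: larkin
Title: Vertical Larynx Kinematics and Intergestural Timing from Real-Time MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying articulatory kinematics in mid-sagittal
    real-time MRI video of the vocal tract. Implements intensity-weighted
    centroid tracking of the larynx inside a fixed vocal-tract region,
    region-of-interest pixel-intensity time series for oral constriction
    gestures, velocity-threshold detection of gesture landmarks (onset, peak
    velocity, target, maximum, offset), and derived intergestural timing
    measures (onset and target lags, larynx displacement and duration).
    Includes a synthetic-data module that renders phantom image sequences
    with known ground-truth trajectories and simulates token-level measure
    tables for a multi-speaker consonant study, plus variability statistics:
    grouped summaries, count-weighted pooling, Brown-Forsythe variance
    tests, a likelihood-ratio test for equality of coefficients of
    variation, lag-duration correlations, and mixed-effects model contracts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tiff,
    yaml,
    jsonlite,
    lmerTest,
    lme4
Suggests:
    testthat (>= 3.0.0),
    car,
    optparse,
    knitr
Config/testthat/edition: 3
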