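Package: villistry
Title: Stereological Quantification of Placental Villi and Vessels with
    Maternal Activity Exposures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis pipeline for CD34-immunostained
    placental sections and accelerometer-measured maternal physical
    activity. Generates synthetic whole-slide images with pixel-level
    ground truth, segments villous tissue and vessel cross-sections by
    colour deconvolution and watershed separation, computes normalized
    stereology metrics (villous density, vessel area, vessel count per
    square millimetre of villous area) on whole sections and on 1-mm
    circular regions, derives moderate-to-vigorous physical activity and
    percent sedentary time from minute-epoch counts with Freedson
    cut-points, and reproduces the tertile, adjusted-regression,
    country-clustered mixed-model and sensitivity analyses of the
    exposure-outcome stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    lme4,
    data.table,
    jsonlite,
    yaml,
    pracma,
    tiff,
    png,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
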