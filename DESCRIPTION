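Package: tric50
Title: Time-Resolved Cell Culture Assay Analysis and Time-Resolved IC50
    Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for time-resolved multi-well cell culture
    assays such as on-line dissolved-oxygen viability monitoring. Provides
    import and validation of time-by-well measurement tables and plate
    layouts, basic formatting (time-unit conversion, trimming, shifting,
    scaling), a two-step correction for sensors with an exponential
    calibration curve (logarithmic recalibration followed by linear
    normalization to a target value), normalization to reference wells,
    replicate aggregation, centred moving-average smoothing, moving-window
    linear slope estimation, and time-resolved IC50/EC50 determination by
    fitting log-logistic dose-response models at every time point. A
    synthetic plate simulator generates fixtures with the statistical
    structure the method assumes, so the whole pipeline is testable without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
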