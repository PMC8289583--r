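Package: adabeat
Title: Heartbeat Classification from ECG with Attributable Features and
    AdaBoost over Random Forests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end toolkit for five-class (AAMI N/S/V/F/Q) heartbeat
    classification from two-lead ambulatory ECG. Provides a labeled synthetic
    ECG generator with known wave boundaries, a WFDB (format 212) reader and
    writer, wavelet-based denoising, R-peak detection and P/QRS/T delineation,
    five attributable feature sets (single- and dual-lead morphology,
    intervals, QRS area, wavelet coefficients), an AdaBoost ensemble with
    random-forest base learners that handles class imbalance by balanced
    weighted bootstraps, and per-class sensitivity/specificity/positive
    predictivity reporting with tidy and ggplot2 output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
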