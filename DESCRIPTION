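Package: glucotrace
Title: Quality Control and Summary Variables for Continuous Glucose Monitoring Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processes continuous glucose monitoring (CGM) sensor exports into a
    standardized set of glucose summary variables for epidemiological analysis.
    Performs quality control (resampling to a one-minute grid by linear
    interpolation, outlier flagging on adjacent differences, complete-days
    restriction or approximal / other-day imputation of missing spans) and derives
    per-day, night-time and day-time summaries across six domains: average glucose
    (trapezoidal AUC per minute), proportions of time in hypo-, normo- and
    hyper-glycaemia under population-specific thresholds, median absolute deviation,
    standardized glycaemic variability percentage (sGVP), a night-time fasting
    glucose proxy, and post-event statistics (time to peak, 1-h and 2-h post-event
    AUC). Includes trace and Poincare plots for manual review, a synthetic CGM
    fixture generator, and a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    readr,
    ggplot2,
    rlang,
    jsonlite,
    optparse,
    yaml,
    zoo,
    withr,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
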