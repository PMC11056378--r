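Package: pehr
Title: Prolonged Elevated Heart Rate and 90-Day Mortality in ICU Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for studying prolonged elevated heart rate (peHR) as a
    risk factor for 90-day mortality in intensive-care cohorts. Provides a
    synthetic ICU cohort generator with known ground truth (irregular
    heart-rate streams, injected sustained-tachycardia episodes, hour-level
    missingness, proportional-hazards survival), hourly-median aggregation
    with inclusion and missingness filters, predictive-mean-matching
    imputation, sliding-window episode detection under standard and
    death-truncated (extended) definitions, Kaplan-Meier and Cox
    proportional-hazards analysis, propensity-score matching and inverse
    probability weighting with balance diagnostics, and a threshold-by-
    duration hazard-ratio sensitivity grid, orchestrated by a reproducible
    end-to-end pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    survival,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
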