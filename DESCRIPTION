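Package: actisleep
Title: Person-Specific Associations Between Wearable-Tracked Physical
    Activity and Sleep Duration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Analysis pipeline for daily wearable-activity-tracker data
    relating prior physical activity to daily light and deep sleep
    duration, at the level of the single participant as well as the
    pooled cohort. Builds lagged aggregate features (mean/min/max of
    steps and activity-intensity durations over the one to three prior
    days), screens them with Spearman correlations under Holm-Bonferroni
    control, searches single-condition subgroups of days scored by
    explained variance, and validates discoveries with a
    swap-randomization null (the distribution of false discoveries).
    Includes a synthetic-cohort generator with optional planted
    activity-to-sleep effects for method validation.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    jsonlite,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
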