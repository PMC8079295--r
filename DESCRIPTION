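Package: shuttlebox
Title: Hypoxia-Avoidance Analysis for Shuttle-Box Choice Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse two-compartment shuttle-box hypoxia-avoidance
    trials with weakly electric fish: construction of stepped dissolved-oxygen
    trial protocols and arena geometry, reading/writing per-second position
    logs, trajectory-derived behavioural metrics (residence in hypoxia, shelter
    use, side changes, distance and velocity), spectral tracking of electric
    organ discharge (EOD) frequency with Q10 temperature prediction, a
    broken-stick (segmented) mixed-model estimator of the hypoxia-avoidance
    threshold, the accompanying hypothesis-test suite (Wilcoxon, Friedman,
    Holm-Bonferroni, repeated-measures ANOVA, EOD mixed models), and a
    synthetic-data generator that emulates the behavioural and electrical
    structure of such trials so the whole pipeline is testable without
    recordings.
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
    lme4,
    lmerTest,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    withr
Config/testthat/edition: 3
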