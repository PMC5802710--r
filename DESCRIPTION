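Package: cbcprofiler
Title: Cutoff Behavioral Criteria Profiling for Elevated Plus Maze Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Individual behavioral profiling of rodent elevated-plus-maze (EPM)
    cohorts using cutoff behavioral criteria (CBC): per-measure percentile
    cutoffs are derived from a control population, each animal is flagged on
    every measure falling in its deviant tail, and animals deviant on at least
    k of m measures are classified as affected. Group affected:unaffected
    distributions are compared to reference proportions with chi-squared
    goodness-of-fit tests, and averaged group effects are analyzed with
    two-way ANOVA (stress x drug) and Bonferroni post hoc comparisons. A
    synthetic-cohort generator with a latent affected subpopulation supports
    validation and power exploration, and an exhaustive integer-count
    inversion utility verifies the internal consistency of reported
    goodness-of-fit statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    car,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
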