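Package: lopforget
Title: Signal-Detection Scoring and Retention-Curve Analysis for
    Levels-of-Processing Forgetting Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing old/new recognition-memory experiments that
    manipulate depth of encoding (levels of processing) and retention interval.
    Scores trial-level data with equal-variance signal detection theory
    (d-prime and criterion, with log-linear correction of extreme rates),
    applies chance-level and outlier exclusion screens, fits four
    two-parameter retention functions (linear, power, exponential,
    logarithmic) by weighted least squares with nested likelihood-ratio tests
    of slope equality between encoding conditions, and runs split-plot and
    factorial ANOVA with Type II sums of squares, partial eta squared,
    Bonferroni and Tukey HSD post hocs, and BIC-approximate Bayes factors.
    Includes a generative simulator of the study designs so every stage of
    the pipeline can be tested and calibrated without participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    car,
    withr
Config/testthat/edition: 3
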