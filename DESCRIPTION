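Package: rpmcstress
Title: Simulation and Analysis of Stress Effects on Rule- and Plan-Based
    Movement Selection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A reproducible psychophysiological analysis pipeline for
    rule-plan-motor-cognition (RPMC) movement-selection experiments run
    around a Trier Social Stress Test manipulation. Provides a synthetic
    cohort generator with planted, recoverable effects; RR-interval
    cleaning and windowed heart-rate / RMSSD marker extraction; area
    under the curve with respect to increase (AUC_I) stress markers for
    heart rate, heart-rate variability, and salivary cortisol; Balanced
    Integration Scores with generalized-ESD outlier filtering and
    participant exclusion; and an inferential layer with mixed-design
    repeated-measures ANOVA, t-tests with Bonferroni correction,
    Lilliefors normality checks, and moderated multiple regression with
    collinearity and autocorrelation diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    withr,
    car,
    lmtest,
    nortest,
    pracma
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
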