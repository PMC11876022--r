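Package: mrmediate
Title: Two-Sample Mendelian Randomization with Mediation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A summary-statistics pipeline for two-sample Mendelian
    randomization (MR) and product-of-coefficients mediation analysis.
    Provides reading, validation and effect-allele harmonization of GWAS
    summary-statistics tables; instrument selection by genome-wide
    significance, greedy LD clumping and F-statistic strength filtering;
    five causal-effect estimators (inverse-variance weighted with fixed
    and multiplicative random effects, MR-Egger, weighted median, simple
    and weighted mode); a sensitivity battery (Cochran Q and I-squared
    heterogeneity, MR-Egger intercept pleiotropy test, leave-one-out,
    Steiger directionality, funnel-plot data); multivariable MR by
    weighted multiple regression; mediation effects with delta-method
    standard errors, the Sobel test and a stepwise significance
    classification (complete mediation, partial mediation, covering
    effect, no mediation); and a seeded generator of GWAS summary
    statistics under a known exposure-mediator-outcome causal structure
    for calibration and parameter-recovery studies.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
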