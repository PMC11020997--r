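Package: mrpath
Title: Two-Sample Mendelian Randomization with Mediation and Bayesian Model Averaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A complete two-sample Mendelian randomization (MR) toolkit for
    summary-level GWAS data: instrument selection (p-value filtering, greedy
    LD clumping, allele harmonization with palindrome handling, F-statistic
    screening), a five-estimator univariable suite (inverse-variance weighted,
    MR-Egger, weighted median, simple and weighted mode), sensitivity
    diagnostics (Cochran's Q, Egger intercept, leave-one-out, MR-PRESSO
    outlier detection), multivariable IVW, Bayesian model averaging over
    candidate risk factors (MR-BMA) with permutation p-values and FDR
    adjustment, and two-step mediation analysis with delta-method intervals.
    Includes a synthetic GWAS summary-statistics generator with known causal
    structure for calibration and validation, and a two-stage pipeline
    orchestrating bidirectional MR, risk-factor prioritization and mediation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    data.table,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pracma,
    jsonlite,
    optparse,
    ggplot2
Config/testthat/edition: 3
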