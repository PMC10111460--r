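Package: mrkit
Title: Two-Sample Mendelian Randomization with Summary Statistics
Version: 0.1.0
Authors@R: person("mrkit", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A complete two-sample Mendelian randomization (MR) toolkit for
    GWAS summary statistics: instrument selection at genome-wide significance,
    allele harmonization with frequency-based inference for palindromic
    variants, greedy LD clumping, instrument-strength statistics (F, R2),
    inverse-variance weighted estimation with multiplicative random effects,
    Wald ratio, MR-Egger regression, the weighted median estimator, MR-PRESSO
    outlier detection, multivariable MR with conditional F-statistics,
    step-wise mediation analysis, and a seeded generator of synthetic GWAS
    summary statistics with known causal, pleiotropic and mediated structure
    for calibration and recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
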