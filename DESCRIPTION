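Package: MRmediate
Title: Two-Sample Mendelian Randomization Screening and Mediation on GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization (MR) on GWAS
    summary statistics: reading and harmonizing per-variant association
    tables, instrument selection (p-value screen, greedy LD clumping and an
    F-statistic weak-instrument filter), the five standard causal-effect
    estimators (inverse-variance weighted, MR-Egger, weighted median,
    weighted mode and simple mode), heterogeneity, pleiotropy and
    leave-one-out diagnostics, many-exposure screening with
    Benjamini-Hochberg false-discovery control and evidence tiering, and
    two-step MR mediation with product-of-coefficients indirect effects and
    proportion mediated.  A seeded summary-level simulator of three-trait
    (exposure, mediator, outcome) causal systems with configurable
    pleiotropy, instrument strength and linkage disequilibrium supports
    calibration and testing without external GWAS downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
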