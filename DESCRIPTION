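Package: telomr
Title: Bidirectional Mendelian Randomization and Mediation Analysis for
    Leukocyte Telomere Length
Version: 0.1.0
Authors@R:
    person("telomr", "developers", email = "telomr@example.org",
           role = c("aut", "cre"))
Description: Tools for studying the causal role of leukocyte telomere
    length (LTL) in complex traits. Implements GWAS summary-statistics
    harmonization against a reference panel, effect standardization to
    the explained-variance scale, LD clumping with region masks and
    allele-frequency concordance checks, Steiger directionality
    filtering (including a multi-trait pleiotropy variant), univariable
    two-sample Mendelian randomization (IVW, Egger, weighted median,
    mode estimators) with Cochran's Q, multivariable MR with conditional
    F-statistics, mediation analysis by product and difference of
    coefficients with simulated confidence intervals, and an
    observational cohort arm (LTL covariate adjustment, per-trait
    regressions, Lasso stability selection, effective number of tests,
    female reproductive-phase model). A synthetic-data module generates
    LD-structured GWAS summary statistics and individual-level cohorts
    with known causal structure so every stage is verifiable by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
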