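Package: pgstrial
Title: Genetics-Augmented Target Trial Emulation with Polygenic Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for running target trial emulations on biobank-style
    cohorts and auditing them with polygenic scores (PGS). Implements the
    full emulation protocol (eligibility, active-comparator designs,
    propensity-score nearest-neighbor matching with a caliper, on-treatment
    follow-up, Cox estimation, estimate agreement against the reference
    randomized trial), staged PGS covariate-balance diagnostics based on
    standardized mean differences, directed-acyclic-graph simulations of the
    bias left when a PGS is used as an imperfect proxy for a confounder
    (with an exact closed-form oracle), two-sample Mendelian randomization
    machinery for confounder detection (instrument selection with linkage
    disequilibrium clumping, inverse-variance-weighted estimation, a
    three-step confounder classification and a direct-effect adjustment),
    and PGS prognostic and predictive enrichment evaluation with
    sample-size calculations. Because individual-level biobank data are
    access-restricted, the package ships a synthetic-data module that
    generates cohorts and GWAS summary statistics with known ground truth,
    making every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
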