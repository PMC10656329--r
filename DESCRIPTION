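Package: btrtrunk
Title: Bradley-Terry Regression Trunks for Paired-Comparison Preference Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits log-linear Bradley-Terry models for complete rankings or
    paired-comparison data with subject-specific covariates, and augments the
    main-effects model with a small set of threshold-interaction terms (a
    regression "trunk") found by an exhaustive deviance-driven split search
    over the covariates. The trunk is pruned by judge-level V-fold
    cross-validation of the case-wise deviance combined with a c standard
    error rule. Includes per-node consensus-ranking summaries (tau-x rank
    correlation and exact median rankings over weak orders), a synthetic
    preference-data generator with transitivity projection, and a simulation
    harness estimating the type I error and power of the pruning rule.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), jsonlite, optparse
Config/testthat/edition: 3
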