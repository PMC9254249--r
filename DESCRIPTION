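Package: oncocohort
Title: Multi-Cohort Comparison of Tumor Somatic Genomes
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for comparing somatic genomic landscapes
    between tumor cohorts. Estimates per-mutation cancer cell fraction by
    binomial deviance minimization and classifies mutation timing; computes
    intra-tumor heterogeneity metrics (percentage of late mutations, MATH,
    Shannon index over subclones); deconvolutes SBS-96 mutation profiles
    into a fixed signature catalog with an iterative retention rule and
    clusters patients into signature groups; scores genome instability and
    arm-level copy-number alteration from integer copy-number segments;
    runs cohort-level Fisher/BH association tests for driver frequencies
    and mutual exclusivity; discovers transcriptomic subtypes by consensus
    non-negative matrix factorization with nearest-template transfer across
    cohorts; and evaluates an integrative random-survival-forest harness
    with repeated feature selection and concordance-index comparison. A
    synthetic two-cohort generator with planted ground truth makes every
    stage testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    ranger,
    survival,
    cluster,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
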