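Package: gxedecomp
Title: Decomposed Gene-Environment Interaction Testing Along Mediated Pathways
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for splitting a gene-environment interaction (GxE) on an
    exposure -> mediator -> outcome pathway into separate "upstream"
    (exposure-to-mediator) and "downstream" (mediator-to-outcome) interaction
    tests, and for quantifying the power advantage of this decomposition over
    the standard single-regression GxE test. Includes a parameterized
    data-generating process and Monte-Carlo power engine with an analytic
    non-central chi-square oracle, heteroscedasticity-robust (sandwich) Wald
    tests of interaction terms, linear structural-equation mediation
    decomposition (total effect, ACME, direct effect) with quasi-Bayesian
    confidence intervals, a synthetic-cohort and linkage-disequilibrium-aware
    variant-panel generator, and a miniature decomposed genome-wide
    interaction study (GWIS) pipeline: phenotype preparation, derived dietary
    exposure weighting, per-variant interaction scans, greedy LD clumping,
    gene-window mapping with Brown's-method gene-level p-value combination,
    and Benjamini-Hochberg false discovery control per pathway.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    GenomicRanges,
    IRanges,
    S4Vectors,
    pracma,
    yaml,
    jsonlite,
    vcfR,
    optparse
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    lmtest,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
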