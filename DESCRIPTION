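Package: allelescore
Title: Allele Scores as Instrumental Variables for Mendelian Randomization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construction of allele scores (genetic risk scores) from genotype
    dosage data - unweighted, internally weighted, cross-validated, and
    externally weighted - and their use as instrumental variables to estimate
    the causal effect of a continuous risk factor on a continuous outcome.
    Provides two-stage least squares, limited information maximum likelihood
    (k-class), composite main-variant-plus-score estimators, first-stage F
    diagnostics, data-driven variant selection, and a Monte Carlo engine that
    simulates genotype-phenotype data under a configurable generating model
    (unequal effects, major-gene/polygene architectures, non-linear effects,
    gene-gene and gene-covariate interactions, and pleiotropic invalid
    instruments) and summarizes bias, coverage and power of each estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
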