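Package: grsxe
Title: Weighted Genetic Risk Scores for Gene-Environment Interaction Testing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Construction of weighted genetic risk scores (GRS) for
    gene-environment (GxE) interaction studies under three weighting
    regimes: external weights from an independent study, internal weights
    from penalized (elastic net) estimates of marginal SNP effects, and a
    train/test scheme in which penalized SNPxE interaction coefficients
    estimated on a training split serve as weights for scoring and testing
    on the disjoint test split. Includes the GRSxE generalized-linear-model
    Wald test, simulation of genotypes under Hardy-Weinberg equilibrium
    with dominant-acting risk SNPs, simulated external weight studies, and
    a replication harness evaluating power, type I error and
    sign-misspecification across train:test balance and minor-allele
    frequency sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    glmnet,
    jsonlite,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
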