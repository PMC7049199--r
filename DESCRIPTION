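Package: exomehub
Title: Rare-Variant Case-Case Classification and Co-Mutation Hub-Gene Discovery
Version: 0.1.0
Authors@R:
    person("Exomehub", "Developers", email = "exomehub@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for contrasting two diagnostic cohorts
    from rare coding variants in whole-exome data. Implements annotation- and
    read-support-based variant filtering into a 0/1/2 genotype table,
    Eigenstrat-style population-structure adjustment of genotypes and
    phenotype (principal axes, per-feature residuals, integer rounding and
    capping), gene-level burden collapsing, boosted-regression-trees
    classification with importance-driven gene extraction (including a
    compiled gradient-boosted tree learner), and a Jaccard/Ward co-mutation
    clustering stage that selects per-disease "hub" gene clusters by their
    unique-carriers-per-gene ratio. Ships a seeded synthetic cohort generator
    with planted ancestry structure, discriminative genes and co-mutation hub
    modules so the whole pipeline is testable without controlled-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    irlba,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0),
    VariantAnnotation,
    withr,
    yaml
Config/testthat/edition: 3
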