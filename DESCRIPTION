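Package: hierpath
Title: Pathway-Based Multivariate Rare-Variant Association via Hierarchical Components
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tests for association between biological pathways and multiple
    correlated quantitative phenotypes using rare variants from sequencing
    studies. Rare variants are collapsed into weighted gene-level burden
    scores, genes are combined into latent pathway components by a
    ridge-penalized generalized structured component analysis fitted with
    alternating penalized least squares, and pathway significance is assessed
    by permutation. Joint multi-phenotype pathway tests are provided by
    correlation-adjusted Fisher combination (Brown/Kost) and by a Wald-type
    quadratic form, with Westfall-Young maxT and Benjamini-Hochberg multiple
    testing correction. Includes a self-contained simulator of rare-variant
    genotypes and phenotypes for type-I-error and power experiments, and
    command-line entry points for reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    SummarizedExperiment,
    GenomicRanges
Config/testthat/edition: 3
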