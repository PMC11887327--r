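Package: mtmat
Title: Phylogenetic Tree-Based Association Tests for Repeatedly Measured
    Microbiome Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tree-based association testing between microbial genera and a
    host phenotype from longitudinal 16S rRNA profiles. Counts are normalised
    to log counts-per-million, pooled along the internal nodes of a rooted
    binary phylogeny into log-ratio covariates, and each node covariate is
    regressed on the phenotype with generalized estimating equations using
    small-sample-adjusted robust score and Wald statistics. Per-node p-values
    are combined by the minimum p-value under its Beta(1, M1) null. Includes
    a synthetic longitudinal count generator and harnesses for type-1 error,
    power, and compositional-bias experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    ggplot2,
    generics,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    yaml,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
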