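Package: trfpathway
Title: Two-Stage Random-Forest Pathway Association Tests for Case-Control
    SNP Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Pathway-level association testing for case-control SNP data
    with random forests. Implements the two-stage random-forest pathway
    test (TRF-pathway), in which all SNPs mapped to a pathway are first
    scored by standardized permutation variable importance, the forest is
    refit on the SNPs exceeding an importance threshold, and the
    out-of-bag prediction error of the second forest is referred to a
    phenotype-permutation null distribution. The single-stage
    random-forest pathway test and a PLINK-style set-based comparator
    (greedy tag-SNP pruning at an r-squared threshold, mean allelic
    chi-square of nominally significant SNPs, permutation p-value) are
    included, together with readers for PLINK additive-dosage text files,
    MAP/GMT/BED annotation formats, SNP-to-pathway mapping by distance
    windows, and a block-correlated genotype simulator with a penetrance
    model supporting main, pairwise, and three-way interaction effects for
    type-I-error and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    rlang,
    stats,
    tibble,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    randomForest,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
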