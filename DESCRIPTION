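Package: genebankgp
Title: Activating Historical Genebank Phenotypes by Genomic Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Curates unbalanced multi-year genebank phenotype records into
    outlier-corrected best linear unbiased estimates (BLUEs) with a mixed
    model allowing year-specific residual variances, adjusts seed lysine
    content for protein content and thousand grain weight by partial
    regression, filters and imputes biallelic marker matrices, builds
    additive (VanRaden) and additive-by-additive epistatic (Hadamard)
    genomic relationship matrices, compares G-BLUP, EG-BLUP, Bayes A and
    Bayesian Lasso genomic prediction models by replicated five-fold
    cross-validation, predicts whole collections, and selects donor
    accessions by two-trait culling levels. Ships a synthetic-data module
    that emulates the statistical structure of historical multi-year
    genebank trials so that every stage is testable without the original
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    Matrix,
    Rcpp,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmmTMB,
    vcfR,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
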