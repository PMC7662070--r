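Package: plsgblup
Title: Multi-Trait Genomic Prediction with PLS-Guided Marker Selection
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genomic prediction for multi-trait breeding programmes in which
    markers are prioritised by two-block canonical partial least squares
    (PLS-CA) between the genotype and trait blocks, converted to 0/1 weights
    by percentile truncation of the marker loadings, and used to build
    weighted genomic relationship matrices for Bayesian multi-trait GBLUP
    fitted by Gibbs sampling with a Kronecker covariance structure. Includes
    pedigree (numerator) and VanRaden relationship matrices, fixed-effect
    phenotype correction and genotype BLUEs, a family-structured population
    simulator with pleiotropic QTL architectures and known truth, k-fold
    cross-validation with in-fold marker selection, deviance information
    criterion model comparison, and an exact Wilcoxon signed-rank test for
    paired fold accuracies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
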