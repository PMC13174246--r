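Package: matchimpute
Title: Reference-Panel Genotype Imputation with Matched-Mask Denoising Autoencoders
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reference-panel-based genotype imputation for low-density
    across-population genomic selection. Missing genotypes are imputed by a
    residual convolutional denoising autoencoder trained per sliding window of
    markers; the corrupted training sets are built by a data-adaptive masked
    marker generation algorithm that matches reference-panel samples to the
    target samples so the network trains on the exact missingness patterns it
    must impute. Supports general imputation (sporadic missingness), one-way
    and two-way reconstructive imputation over marker-set algebra between two
    populations and a panel, concordance/r-squared accuracy metrics with
    minor-allele-frequency breakdowns, an LD-structured haplotype-mosaic
    genotype simulator, and a GBLUP genomic predictor for end-to-end
    across-population prediction demonstrations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    data.table,
    vcfR,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
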