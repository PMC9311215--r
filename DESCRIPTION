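Package: adaptscan
Title: Candidate Loci for Local Adaptation in Structured Populations
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Detects candidate loci for local adaptation from SNP genotype
    data sampled across structured populations. Implements locus and
    individual filtering, Nei and Weir-Cockerham differentiation statistics,
    allele frequency spectra, directional relative migration, a PCA-based
    Mahalanobis outlier scan with genomic inflation correction, redundancy
    analysis (RDA) genotype-environment association with per-variable
    q-values, Storey-Tibshirani q-value estimation, geometric-mean
    combination of q-values across methods, and a random-environment null
    control that classifies candidates as high or low confidence. Ships a
    hierarchical Balding-Nichols simulator of clades, populations and
    environmental gradients so the whole pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    vegan
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
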