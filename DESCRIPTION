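Package: grainQG
Title: Multi-Environment Quantitative Genetics: Mixed-Model GWAS and
    Genomic Prediction for Inbred Crop Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end quantitative-genetics toolkit for diversity panels
    of inbred crop varieties phenotyped in multiple environments. Covers
    REML variance components and broad-sense heritability from
    per-environment adjusted entry means, best linear unbiased estimations
    (BLUEs), Fisher-z averaged correlations, SNP marker quality control
    and mean imputation, linkage-disequilibrium decay, PCA-based
    population-structure assessment, mixed-linear-model genome-wide
    association with kinship and principal-component correction,
    Benjamini-Hochberg FDR control, explained-genotypic-variance
    decomposition, and genomic prediction by GBLUP, BayesB and
    reproducing-kernel Hilbert-space regression under repeated k-fold
    cross-validation. Includes a synthetic-data generator with known
    ground truth for validation, and haplotype/nucleotide-diversity
    statistics for candidate-gene alignments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    Biostrings,
    lme4,
    vcfR,
    Rcpp,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
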