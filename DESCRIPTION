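Package: svgblup
Title: Structural-Variant Imputation Evaluation and GBLUP Analysis for Dairy Cattle
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative-genetic analysis of imputed structural
    variants (SVs) in dairy cattle populations. Provides merging and
    validation of SV call sets by interval overlap, 0/1/2/5 genotype
    encoding with read-depth filtering, Yang-style genomic relationship
    matrices from SNP or SV dosages, average-information REML with EM
    fallback for two-component GBLUP models, mixed-linear-model GWAS with
    multi-trait chi-square meta-analysis and an FDR estimator, masking-based
    cross-validation of SV imputation accuracy, repeated k-fold
    cross-validation of genomic prediction accuracy, and a seedable
    synthetic-population generator (founder-mosaic haplotypes with breed
    admixture, sire-son pairs and twice-sequenced duplicates) so every
    stage is testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation
Config/testthat/edition: 3
RoxygenNote: 7.3.3
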