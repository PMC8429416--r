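Package: epitwas
Title: Epigenetically Informed Transcriptome-Wide Association Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements a transcriptome-wide association study (TWAS)
    pipeline in which gene expression prediction models are trained from
    cis genotypes using annotation-stratified SNP sets (eQTL P-value
    thresholds crossed with epigenetic features such as TFBS, DHS and
    chromatin-state segmentations), penalized regression (lasso and
    elastic net) under ten-fold cross-validation, and a cis-heritability
    filter. Trained weights are tested against GWAS summary statistics
    through an LD reference panel, with weight-permutation empirical
    p-values, joint and conditional modeling of multi-gene regions,
    stratified LD score regression for partitioned heritability of TWAS
    gene sets, and permutation-based catalog enrichment. A synthetic-data
    module generates block-LD genotype panels, annotations, expression and
    consistent summary statistics so the full pipeline can be exercised
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
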