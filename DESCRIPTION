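Package: sparseDMR
Title: Differential Methylation Analysis for Sparse Invertebrate
    Methylomes with Paired Designs
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Whole-genome bisulphite sequencing (WGBS) differential
    methylation analysis tailored to sparse, mosaic invertebrate
    methylomes and paired (e.g. clonal, mother-matched) designs.
    Provides methylation-call import for Bismark cytosine-report and
    coverage formats, bisulphite non-conversion read filtering, SNP
    masking of polymorphic CpGs, coverage filtering, local-likelihood
    (BSmooth-style) smoothing, per-CpG paired t statistics with
    variance flooring, candidate region detection, autocorrelation-aware
    Stouffer-Liptak region p-value combination with false discovery
    rate control, replicate clustering with bootstrap support, gene and
    exon overlap annotation, and Fisher-based GO term enrichment with a
    hierarchy-aware elim option. A synthetic-data generator emulates
    the sparse mosaic methylome (low global CpG methylation concentrated
    in gene bodies, 8-12x coverage, conversion failure, mother-correlated
    replicates, planted differentially methylated regions) so the whole
    pipeline can be exercised and validated at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    data.table,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer,
    ape
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
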