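Package: maturekit
Title: Temporal Transcriptomic and Chromatin Maturation Analysis for
    Neuronal Time Courses
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of neuronal maturation time courses from bulk nuclear
    RNA-seq and ATAC-seq. Provides median-of-ratios normalization, an
    expressed-gene CPM filter, a negative-binomial exact test for consecutive
    timepoint contrasts, sample PCA, temporal dynamics summaries and
    keyword-based effector categorization, two-stage non-negative least
    squares deconvolution of bulk profiles against cluster-merged single-cell
    references, in vivo versus in vitro fold-change concordance
    classification, interval-based chromatin peak dynamics (gain/loss,
    TSS proximity, conservation averaging), and a seeded synthetic-data
    generator with known ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    rtracklayer,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: RNASeq, ATACSeq, GeneExpression, Normalization,
    DifferentialExpression, SingleCell, Software
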