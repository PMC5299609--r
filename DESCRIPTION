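Package: adipoDiff
Title: Integrative Analysis of Brown Adipocyte Differentiation Time Courses
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to prioritize transcriptional regulators of brown fat
    cell differentiation from time-course RNA-seq and H3K27ac ChIP-seq
    region counts, transcription factor peak sets, cross-panel expression
    correlation, and multiplexed UMI-barcoded knockdown mRNA-seq. Provides
    trimmed-mean-of-M-values scaling, precision-weighted moderated
    differential testing, fuzzy c-means trend clustering with validity
    scanning, region-set algebra with differential-acetylation catalogs,
    position weight matrix scanning with hypergeometric enrichment and
    summit-centrality profiles, correspondence analysis, barcode/UMI
    demultiplexing and counting, a curated gene regulatory network overlay,
    and fully seeded synthetic-data generators so that every stage is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    Biostrings,
    jsonlite,
    yaml,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR,
    limma,
    e1071,
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Epigenetics, GeneExpression, DifferentialExpression,
    Clustering, MotifDiscovery, Sequencing
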