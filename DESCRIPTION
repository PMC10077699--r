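Package: m6Aflow
Title: MeRIP-Seq Differential Methylation and Co-Expression Analysis for
    Intramuscular Fat Epigenomics
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end analysis toolkit for MeRIP-seq (m6A-seq) studies
    of quantitative traits, built around a porcine intramuscular-fat study
    design with High and Low phenotype groups.  Provides reference peak
    panel construction from per-group peak calls, IP/input normalized-depth
    quantification of per-peak methylation, t-test based differential
    methylation, expression filtering, TPM and median-of-ratios
    normalization, differential expression, PCA sample screening,
    transcript-region annotation with metagene profiling and RRACH motif
    scanning, a weighted co-expression network (soft threshold, topological
    overlap, module eigengenes, module-trait correlation, hub-gene
    screening), co-differential integration of methylation and expression,
    and hypergeometric over-representation analysis with Holm correction.
    A synthetic-data generator with known planted truth makes every stage
    testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    SummarizedExperiment,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    rtracklayer
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Epigenetics, Sequencing, DifferentialMethylation,
    GeneExpression, Network, Software
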