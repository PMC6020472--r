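Package: splicemeta
Title: Meta-Analysis of Therapy-Induced Spliceosome Suppression Across
    Expression Datasets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for detecting direction-consistent,
    therapy-induced pathway changes across many two-group expression
    datasets by combining per-dataset p-values with Wilkinson's
    order-statistic method, correcting with the Benjamini-Hochberg false
    discovery rate, and requiring an exclusive up- or down-regulation
    direction in every study.  Companion modules parse rMATS-style
    differential-splicing tables and count recurrent events across
    samples, scan retained introns for in-frame premature stop codons,
    softly cluster z-scored expression time courses with fuzzy c-means,
    build transcription-factor co-regulation networks from promoter
    binding intervals and Spearman co-expression, and provide
    hypergeometric over-representation, Fisher exact overlap, and Venn
    region summaries.  A synthetic-data module generates every input
    class with known ground truth so the full pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    e1071,
    mclust
Config/testthat/edition: 3
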