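Package: mirTarNet
Title: miRNA-Gene Regulatory Network Inference for Developmental Time Courses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers miRNA-gene regulatory networks from small-RNA sequencing
    count data collected over an ordered developmental time course. Provides
    negative-binomial differential expression with median-of-ratios
    normalization and a Wald test, temporal pattern classification across
    adjacent and long-range time-point comparisons, anti-correlation based
    verification of predicted miRNA targets against a differential mRNA
    table, one-sided hypergeometric (and EASE-style) gene-set
    over-representation analysis, bipartite network assembly with chord and
    Sankey export, delta-delta-Ct qPCR quantification, and a synthetic-data
    generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
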