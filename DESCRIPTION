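Package: coexqc
Title: Benchmarking Data Processing Workflows for Gene Co-Expression
    Networks from RNA-Seq Count Collections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for turning multi-study RNA-seq count collections into
    cell-type-specific gene co-expression networks under a grid of
    processing workflows (between-sample normalization, batch effect
    correction, correlation measure), for scoring each network with eight
    annotation-enrichment quality measures combined into a single
    PCA-derived Quality score, and for meta-analyzing which processing
    choices drive network quality by linear regression. Includes a
    negative-binomial synthetic-data generator with known ground-truth
    co-expression modules, batch effects and matched annotation sets,
    implementations of six normalization procedures (TMM, CPM, upper
    quartile, median, simplified regularized log, quantile), linear and
    empirical-Bayes location-scale batch correction with
    confounding-aware partitioning, hypergeometric gene-set enrichment
    with Benjamini-Hochberg control, and workflow ranking,
    cross-validation and paired-comparison analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    limma,
    sva
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
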