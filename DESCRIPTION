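Package: stagenet
Title: Staged-Embryo Transcriptome Analysis with Weighted Co-Expression
    Modules
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for staged (time-course) embryo
    transcriptomes: detection thresholding and consecutive-stage
    negative-binomial differential expression with median-of-ratios
    normalization; K-means expression-pattern clustering with
    Bonferroni-corrected pattern assignment; weighted gene co-expression
    network construction (soft-threshold adjacency, topological overlap,
    dynamic tree cut, module eigengenes, eigengene-correlation merging);
    stage-specific module calling and hub-gene identification; permutation
    module-preservation Z statistics; and cross-species module-overlap
    testing via ortholog groups and the hypergeometric test. Includes a
    synthetic staged-transcriptome generator with planted co-expression
    modules so every stage of the pipeline is testable with known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    MASS,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
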