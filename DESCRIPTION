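Package: germnet
Title: Gene Regulatory Network Inference from Germ-Layer Differentiation
    Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing bulk RNA-seq time courses of embryonic stem
    cell differentiation towards the three germ layers: depth and
    median-filter based normalization of read counts, differential gene sets
    and their intersections, average-linkage clustering and principal
    component trajectory maps with cross-platform projection of external
    expression profiles, position weight matrix scanning of proximal
    promoters, motif activity response modelling of log expression on
    promoter site counts, construction of a directed signed transcription
    factor network gated on activity-expression correlation, enumeration of
    feed-forward loops and dense overlapping regulons, and a resampling gene
    set enrichment test. A synthetic data generator reproduces the
    statistical structure the pipeline assumes and provides ground truth for
    recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    yaml,
    Biostrings,
    ape,
    fgsea,
    generics
Suggests:
    testthat (>= 3.0.0),
    igraph,
    cluster,
    withr
Config/testthat/edition: 3
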