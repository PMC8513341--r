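Package: stemmiR
Title: Small RNA Read Processing, Stem-Loop miRNA Discovery and
    Median-Reference Count Normalization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An end-to-end toolkit for plant small RNA sequencing studies:
    adapter/junk/length read cleaning and collapsing to unique sequences,
    partitioning of reads into non-coding RNA and repeat classes, known
    miRNA identification (including opposite-arm p5/p3 species), novel
    miRNA discovery from genomic stem-loop windows screened by an
    eleven-criterion hairpin filter, median-reference regression
    normalization of per-library copy numbers, t-test and one-way ANOVA
    differential expression, plant-style miRNA target-site scoring, and
    hypergeometric GO/KEGG term enrichment. A synthetic-data generator
    emulates a two-line by four-stage replicated seed-development design
    so every stage of the pipeline can be validated against a planted
    ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    graphics,
    methods,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
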