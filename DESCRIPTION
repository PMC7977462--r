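Package: epiJSD
Title: Read-Level Epiallele Heterogeneity Analysis for Bisulfite Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies intratumor DNA methylation heterogeneity from
    bisulfite sequencing at the level of 4-CpG epialleles. Reduces
    Bismark-style alignments to read-level methylation patterns, compares
    the 16-pattern distributions of two samples with a Jensen-Shannon
    dissimilarity (a bounded metric), calls differential and
    sample-specific epialleles against fitted normal null thresholds via a
    composite specificity index, and summarizes per-sample heterogeneity
    with epipolymorphism and a binned methylation-heterogeneity AUC.
    Includes a multi-region RRBS cohort simulator with ground truth and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings,
    IRanges,
    Rsamtools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
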