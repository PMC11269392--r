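Package: methyldx
Title: Sparse-CpG Methylation Classification and Copy-Number Profiling for
    Low-Pass Nanopore Sequencing of CNS Tumors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for DNA methylation-based classification of central nervous
    system tumors from sparse, low-pass nanopore whole-genome sequencing.
    Methylation calls are binarized and aligned to a binary CpG reference
    atlas, classified with a neural network trained under random feature
    masking so that arbitrarily sparse CpG coverage is handled natively, and
    reported as per-class softmax scores aggregated to methylation class
    families. Includes ROC-based calibration of the diagnostic score cutoff,
    binned copy-number profiling with reference subtraction and recursive
    binary segmentation, focal-event detection, grid-search tumor purity
    estimation from segment log-ratios, and a synthetic-data generator with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
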