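Package: cfbrain
Title: Brain-Derived Cell-Free DNA Quantification from Targeted
    Bisulfite Amplicon Sequencing
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for measuring brain-derived cell-free
    DNA (cfDNA) in plasma from targeted bisulfite amplicon sequencing.
    Covers selection of cell-type-specific unmethylated CpG markers from
    methylation array beta values, demultiplexing and quality filtering of
    bisulfite PCR reads, edit-distance assignment of reads to amplicon
    targets, per-molecule CpG methylation calling, counting of fully
    unmethylated molecules, conversion to genome equivalents per mL of
    plasma, per-cell-type and combined brain scores, and cohort-level
    statistics (Mann-Whitney comparisons, ROC/AUC with DeLong or bootstrap
    confidence intervals, sensitivity at fixed specificity, antipsychotic
    dose-equivalent conversion and a drug-correlation screen with
    multiple-testing correction). A synthetic-data module simulates
    bisulfite-converted amplicon reads from controlled cell-type mixtures
    and full case/control cohorts, so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    pROC,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
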