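Package: methrecover
Title: Methylation-Recovery Analysis for MeDIP-seq Rescue Experiments
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Quantifies restoration of DNA methylation in rescue experiments
    profiled by MeDIP-seq (methylated-DNA immunoprecipitation sequencing).
    Implements reads-per-kilobase scaling followed by an affine log2
    normalization anchored on invariant control regions, the per-region
    methylation-recovery (MR) statistic with class-level boxplot summaries
    and Spearman methylome correlation, clone-based bisulfite CpG calling
    with conversion-rate quality control, Pfaffl efficiency-corrected qPCR
    fold changes and HPLC percent-5mC quantification. A seeded synthetic-data
    generator emulates wild-type, knockout-baseline and partial-rescue
    methylomes with overdispersed counts so the whole pipeline is testable
    without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
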