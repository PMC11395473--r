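Package: masterscan
Title: Master Regulatory Transcription Factor Screening in Phytohormone
    Pathway Promoters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies candidate master regulatory transcription factors of
    phytohormone (salicylate, jasmonate, abscisic acid, ethylene) biosynthesis
    and signaling genes. Scans TSS-anchored promoter windows (-5000..+1000)
    with JASPAR-style position weight matrices at an exact p-value stringency
    computed by dynamic programming over the discretized score distribution,
    screens hits across pathway gene groups by an intersection rule,
    tallies upstream and downstream binding regions, and links master factors
    to CPM-based pairwise differential expression called against a
    simulated-replicate noise distribution (M-D procedure). Ships a fully
    seeded synthetic-data generator (promoters with planted motif instances,
    negative-binomial count tables with planted fold changes) so the entire
    pipeline is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    edgeR,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
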