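Package: sheathrna
Title: Quantifying mRNA Localization to Myelin Sheaths and Discovering
    3' UTR Localization Motifs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis toolkit for studying how mRNAs localize to myelin
    sheaths. Implements quantification of single-molecule FISH and MS2
    reporter imaging (rolling-ball background subtraction, SD thresholding,
    particle analysis with integrated density, line-scan spatial enrichment
    profiles and their statistics), transcriptome filtering pipelines that
    define a myelin transcriptome and candidate 3' UTRs from FPKM tables,
    and a motif workflow: ZOOPS expectation-maximization motif discovery,
    position-weight-matrix log-odds scanning with exact p-values by dynamic
    programming, region classification of motif occurrences, and enrichment
    testing against shuffled control sequences. Ships seeded synthetic-data
    generators (fluorescence stacks with ground-truth spots, transcript
    sets with planted motifs, replicate abundance tables with planted
    enrichment) so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
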