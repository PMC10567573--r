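Package: multigps
Title: Multiplexed GPS/CRISPR Reporter Screen Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for multiplexed Global Protein Stability (GPS)
    CRISPR screens, in which libraries of GFP-fusion substrates and sgRNAs
    targeting E3 ubiquitin ligases are combined on one vector and deconvoluted
    by paired-end sequencing. Provides paired-read substrate-by-guide
    demultiplexing, protein stability index (PSI) and delta-PSI computation
    from FACS-bin-sorted count tables, gene-level E3 hit calling in one-bin
    (enrichment rank permutation) and six-bin (Mann-Whitney) formats,
    saturation-mutagenesis degron mapping, barcode-to-ORF assignment, and
    permutation tests for overlap with protein-interaction edge lists. A
    generative simulator with planted E3-substrate ground truth makes every
    stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
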