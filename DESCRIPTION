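Package: hadalomics
Title: Community Composition, Metabolic Traits, and Virus-Host Association
    for Deep-Sea Sediment Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the downstream, tabular stages of a sediment
    metagenome survey: aggregation of per-read taxonomic assignments into
    relative sequence-abundance tables, quality filtering and tiering of
    metagenome-assembled genomes (MAGs), pathway module-completeness
    scoring and metabolic lifestyle classification from marker-gene
    annotations, three-signal virus-host association (sequence similarity,
    CRISPR spacer matching, and tetranucleotide composition distance) with
    bipartite network summarisation, auxiliary-metabolic-gene (AMG)
    flagging on viral contigs, marker-hit filtering and alignment trimming
    utilities, and a seeded synthetic-metagenome generator with a known
    truth manifest so every stage can be verified end to end.
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
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
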