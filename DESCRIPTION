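Package: metabolons
Title: Genomic Metabolons and Candidate Genes for Orphan Enzymes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects genomic metabolons, groups of co-localized genes whose
    products catalyze reactions connected by shared main compounds, in
    prokaryote genomes, and proposes candidate genes for gap and orphan
    reactions without using sequence similarity. A two-layer data graph
    (gene adjacency, reaction adjacency, known gene-reaction associations)
    is partitioned into maximal common connected components with gap
    tolerance via partial transitive closures; candidate associations are
    weighted by minimal path length, integrated across organisms through
    gene families, scored, and ranked. Includes a synthetic-corpus
    generator with planted operon and pathway structure and a systematic
    orphanization benchmark with precision-recall curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
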