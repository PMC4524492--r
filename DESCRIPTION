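Package: plastarch
Title: Comparative Architecture of Chloroplast Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of chloroplast genome architecture
    in green algae: signed circular gene orders and the sidedness index,
    detection of the large inverted repeat and quadripartite partitioning,
    exact signed reversal distances between gene orders via the
    Hannenhalli-Pevzner breakpoint graph, Dollo-parsimony mapping of binary
    genomic characters (gene adjacencies, inverted-repeat presence) on a fixed
    rooted tree, exact repeat landscapes with non-overlapping masking, and
    nucleotide composition summaries including G+C content by codon position.
    Ships a transcription of a 38-taxon pedinophycean/trebouxiophycean study
    table and phylogeny, and a seeded plastome evolution simulator (inversions,
    inverted-repeat boundary shifts and losses, repeat insertions) that
    produces GenBank-style fixtures with a replayable truth log.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tools,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
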