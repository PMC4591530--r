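Package: metasig
Title: Annotation-Independent Signature Comparison for Shotgun Metagenomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to compare shotgun metagenomes without reference
    annotation: dinucleotide relative-abundance odds ratios and Karlin
    delta distances (reported on a x1000 scale), tetranucleotide z-scores
    compared by Pearson correlation, Ward clustering of taxonomic
    abundance profiles with newick export, autotroph-to-heterotroph
    abundance ratios, and summaries of virulence-factor similarity hits
    with per-base-pair normalization. Includes a fully seeded
    synthetic-data generator (Markov-chain genomes, pyrosequencing-style
    read libraries, group-structured abundance tables, and
    category-structured hit tables) so the whole pipeline can be
    exercised without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    methods,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    ape,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
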