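Package: dechip
Title: De Novo ChIP-Seq Analysis Without a Reference Genome
Version: 0.1.0
Authors@R:
    person("dechip", "developers", email = "dechip@example.org", role = c("aut", "cre"))
Description: Reference-free analysis of transcription-factor ChIP-seq
    experiments. Raw case reads are assembled into 'ChIPtigs' (contigs
    representing putative bound regions) with either a Velvet-style de
    Bruijn graph assembler adapted for double-stranded ChIP fragments or
    a consensus profile assembler with online count updates and an
    entropy stopping rule. Case and control reads are then mapped back to
    the ChIPtigs, which are ranked by a binomial enrichment tail
    probability, and binding motifs are discovered in the top-ranked
    ChIPtigs by discriminative IUPAC-word search scored with Fisher's
    exact test. A seeded simulator of ChIP-seq experiments with planted
    motif sites makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    data.table,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
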