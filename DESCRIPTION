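Package: regulonscout
Title: Comparative Genomics of Transcription-Factor Regulons in Bacteria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for inferring transcription-factor regulons across bacterial
    genomes by comparative genomics, modelled on the analysis of the LexA (SOS
    response) regulon of the Verrucomicrobia. Builds binding-motif models from
    aligned sites and scores sequences with the sequence-information (Ri)
    method; discovers palindromic motifs de novo with a zero-or-one-occurrence
    EM algorithm; predicts and revises operons from intergenic distances;
    detects orthologs as reciprocal best hits of local protein alignments and
    summarizes species relationships with a distance-based transcription-factor
    tree; assembles a cross-species regulon matrix; analyses tandem
    binding-site arrangements and the emergent junction motifs they generate;
    and generates fully annotated synthetic genome communities with planted
    regulons for end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml
Config/testthat/edition: 3
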