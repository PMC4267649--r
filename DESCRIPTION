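Package: structmotif
Title: Structure-Based Prediction of Transcription Factor Binding Motifs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the DNA-binding motif of a transcription factor from a
    co-crystal (or externally modeled) TF-DNA complex structure. Curates the
    complex and trims the DNA to the protein-contacting stretch, threads every
    possible k-mer onto the fixed sugar-phosphate backbone by anchor-triad base
    replacement, scores each threaded complex with a distance-dependent
    residue-specific knowledge-based potential, converts scores to relative
    binding affinities and a position weight matrix, compares and clusters
    motifs with decoy-calibrated similarity Z-scores, and scans promoter
    sequences for putative target genes. Includes a synthetic-fixture generator
    (toy complexes, planted potentials, random motif sets, toy genomes) so the
    whole pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    bio3d,
    data.table,
    jsonlite,
    BiocGenerics,
    Biostrings,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    S4Vectors,
    rtracklayer,
    ape
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    optparse
Config/testthat/edition: 3
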