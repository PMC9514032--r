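Package: ttcassettes
Title: Mining Transcription-Translation Gene Cassettes in Prokaryotic Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A comparative-genomics pipeline for discovering and quantifying
    gene cassettes (operonic gene runs) that jointly encode transcription- and
    translation-machinery genes across prokaryotic genomes. Provides readers for
    per-genome annotation tables (GFF3 or TSV) and operon tables, a curated
    synonym-aware catalog of transcription/translation genes, four-way cassette
    categorization, three-way genome-occurrence ranking (gene, function, COG),
    an intergenic-distance based logistic operon-pair classifier, corpus-internal
    linkage scores (gene fusion, neighborhood, co-occurrence) with thresholded
    candidate-cassette extraction and k-means bipartition, cassette-matching and
    genome-counting rules (exact, reordered, subset), hypergeometric
    over-representation analysis with Benjamini-Hochberg FDR control, taxonomic
    distribution summaries, and a ground-truth corpus simulator with a manifest
    oracle for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    igraph,
    Biostrings,
    rtracklayer,
    S4Vectors,
    BiocGenerics,
    GenomicRanges
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
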