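Package: panmatrix
Title: Pan-Genome Construction, Curation and Visualisation from Whole-Genome Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds bacterial pan-genomes from multiple whole-genome
    alignments via a SuperGenome coordinate system: parses XMFA alignments,
    establishes bidirectional maps between each genome's coordinates and a
    shared alignment axis, lifts GFF3 gene annotations onto that axis, and
    groups overlapping genes into pan genes (ortholog groups) refined by
    pairwise sequence identity. The resulting presence-absence matrix
    supports core/orphan/dispensable classification, validated aggregation
    and deaggregation of complementary pan genes with undo and a replayable
    interaction history, automatic detection of aggregation candidates from
    TIGRFAM labels or consensus descriptions, and a strand-aware glyph
    matrix rendering exportable to SVG, PDF and bitmap formats. A
    deterministic synthetic-data generator provides toy genomes, alignments
    and annotation sets with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    S4Vectors,
    igraph,
    rtracklayer,
    grDevices,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    xml2,
    png,
    jsonlite
Config/testthat/edition: 3
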