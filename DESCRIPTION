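Package: GaudiHiC
Title: Spatial Projection of Chromatin Accessibility onto Hi-C Contact
    Structure and Differential Transcription-Factor Occupancy
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Projects chromatin-accessibility signal onto a two-dimensional
    Kamada-Kawai embedding of a balanced Hi-C contact matrix ("Gaudi plots"),
    derives per-bin spatial occupancy polygons by Voronoi clipping of buffer
    discs, selects genomic bins spatially proximal to a transcription start
    site, retains bases carrying the top fraction of sequence-model
    contribution scores, scans the retained regions for transcription-factor
    binding motifs, and reports differential family-level motif occupancy
    between two conditions (e.g. vehicle versus treatment). Ships a
    synthetic-data module that emulates TAD-structured contact matrices with
    power-law distance decay, condition-specific accessibility peaks,
    footprint-shaped contribution tracks, and genomes with planted motif
    instances, so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    igraph,
    jsonlite,
    withr,
    IRanges,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    GenomicRanges
Config/testthat/edition: 3
biocViews: HiC, ATACSeq, Epigenetics, MotifAnnotation, Visualization
RoxygenNote: 7.3.3
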