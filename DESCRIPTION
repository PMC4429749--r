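Package: mirRegNet
Title: Plant miRNA Transcription Start Sites, Promoter Elements and
    Regulatory Network Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts plant microRNA transcription start sites from
    chromatin and TSS-tag evidence (H3K4me3, H3K9ac, nucleosome H3,
    full-length-cDNA TSS tags) plus core promoter motifs with a trained
    support vector machine; scans the 10 kb upstream of each pre-miRNA and
    ranks TSS candidates. Detects trans-regulatory elements by Match-style
    position weight matrix scanning of promoters, co-occurring TFBS
    (coTFBS) frequencies across coexpressed gene groups and hypergeometric
    over-representation p-values. Reconstructs miRNA-centric regulatory
    networks from miRNA-target interactions, expression correlations,
    depth-first-search expansion to indirect targets and GO term
    enrichment, with Cytoscape-compatible export. Ships a fully seeded
    synthetic-data generator emulating every input with planted ground
    truth, so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    graphics,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    e1071,
    igraph,
    jsonlite,
    yaml,
    limma
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Software, Transcription, GeneRegulation, NetworkInference,
    Epigenetics, MotifDiscovery
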