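Package: mitostruct
Title: Structural Analysis of Multipartite Plant Mitochondrial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the structural analysis of multipartite circular
    mitochondrial genomes such as those of potato: detection of large
    intramolecular repeat pairs, enumeration of repeat-mediated
    recombination products (sub-genomic circles and inversion isoforms),
    validation of predicted recombinant junctions with long reads
    ("reverse read mapping"), pairwise molecule comparison with
    translocation and breakpoint flanking-repeat discovery, in silico PCR
    for mitochondrial DNA typing, and gene content/ORF inventories.
    Ships a synthetic mitogenome and long-read simulator with
    machine-readable truth for testing and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer,
    data.table
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
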