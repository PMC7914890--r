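Package: stablefrag
Title: Discovery, Clustering and Quantification of Stable Small RNA
    Processing Products from Deep-Sequencing Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for detecting stable RNA processing
    products (small ncRNAs, tRNA-derived fragments, rRNA fragments) in
    small-RNA deep-sequencing libraries. Reads are quality- and
    adapter-trimmed, aligned ungapped to a reference genome with
    all-alignments reporting, reduced to best-stratum placements, and
    paired-end reads are merged into full-insert pseudo single-end
    records with genomic gap filling and 3'-oligo(A) awareness.
    Products are then predicted per library by size fractionation and
    peak calling on 5'/3' end densities, reduced across libraries by
    overlap and sequence/contig clustering, and quantified with RPM and
    per-biotype RPM layers. A synthetic-data module generates toy
    genomes, annotations and adaptered reads with planted products so
    the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
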