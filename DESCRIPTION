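Package: mitocompare
Title: Comparative Analysis of Fungal Mitochondrial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of annotated circular fungal
    mitochondrial genomes: base composition and AT/GC strand skews, region
    partitioning and between-genome size-contribution decomposition, codon
    usage and relative synonymous codon usage (RSCU) under selectable NCBI
    genetic codes (default 4, mold mitochondrial), REPuter-style long-repeat
    detection in four orientations with Hamming mismatch tolerance, MISA-style
    microsatellite (SSR) detection, Kimura-2-parameter distances and
    Nei-Gojobori (1986) Ka/Ks with selection classification, intron
    position-class (Pcl) assignment against a reference coding sequence with
    common/rare classification across species, and circular gene-order
    comparison by signed breakpoint distance. Includes readers and writers
    for GenBank flat files, FASTA and a tabular feature-table dialect, plus a
    deterministic synthetic-mitogenome generator with truth manifests for
    end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    Rcpp,
    jsonlite,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ape,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
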