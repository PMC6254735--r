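Package: createscan
Title: Pathway-Scale Deep Scanning Mutagenesis with Trackable Editing Cassettes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design, quantification, and statistical analysis tools for deep
    scanning mutagenesis experiments that couple CRISPR editing cassettes to
    plasmid barcodes. Selects mutagenesis sites within a distance shell of
    declared binding atoms in a protein structure, enumerates full codon
    saturation designs with preferred codons, and assembles 230-nt editing
    cassettes carrying a gRNA spacer, a 118-nt homology arm, and a synonymous
    PAM-disrupting substitution. Counts cassette barcodes in merged amplicon
    reads with two-tier identity matching, computes replicate log2 enrichment
    scores combined by count-weighted averaging, calls significance against a
    bootstrap null built from synonymous designs, and verifies genomic edits
    from amplicon windows (coverage and editing-efficiency estimates). A
    seeded selection simulator with configurable editing efficiency, escaper
    cells, and per-design fitness provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    bio3d,
    dplyr,
    methods,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
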