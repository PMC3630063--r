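Package: mirpare
Title: Plant Small RNA Discovery, Exact-Test Differential Expression and
    Degradome Target Validation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the computational analysis of plant small-RNA
    sequencing experiments with two conditions and no replicates: adapter
    cleaning and read collapsing into unique tags, perfect-match genome
    mapping and structural-RNA annotation, hairpin-precursor excision and
    folding under an oracle-checkable stacking energy model, Meyers-style
    novel miRNA calling with miRNA* (star) evidence and 2-nt 3' overhang
    geometry, the exact two-library count test with RPM normalisation and
    log2 ratios, six-rule plant miRNA target prediction with a position
    penalty score and duplex energy-ratio filter, and degradome (PARE)
    cleavage-site detection with category I/II/III classification and
    shuffled-miRNA significance. A seeded synthetic-data generator plants
    hairpins, expression fold changes and cleavage signals with full ground
    truth so that every stage is testable without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
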