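Package: horscan
Title: Detection of Alpha-Satellite Higher-Order Repeats in Genome Assemblies
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects and classifies alpha-satellite higher-order repeats
    (HORs) in centromeric regions of genome assemblies. Extracts ~171 bp
    alpha-satellite monomers by consensus alignment, classifies them into
    monomer types under an edit-distance divergence threshold, computes
    monomer-distance (MD) diagrams and repeat-period frequency tables,
    segments tandem arrays into canonical and variant HOR copies (including
    cascading HORs whose units repeat monomer types internally), builds
    column-aligned multi-row HOR schematics, and reports consensus sequences
    and divergence statistics. Ships a simulator for alpha-satellite arrays
    with known ground truth so every stage of the pipeline can be validated
    end to end.
License: Artistic-2.0
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    S4Vectors,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
biocViews: Alignment, Annotation, RepeatDetection, SequenceMatching
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
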