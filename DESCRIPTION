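Package: organellum
Title: Organelle Genome Finishing, Variant Statistics and Whole-Plastome
    Barcoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Finishing and comparative analysis of plant organelle genomes:
    reconstruction of the quadripartite chloroplast genome (inverted-repeat
    detection, expansion of a collapsed inverted-repeat scaffold, canonical
    rotation and strand), finishing of a circular mitochondrial genome from
    scaffolds and chloroplast-subtracted reads, reference mapping with
    length/similarity acceptance thresholds, quality-voting consensus and
    variant calling with SNP-frequency statistics, alignment-based variant
    matrices with species-specific (whole-plastome barcode) filtering and
    variation-hotspot window scans, chloroplast-like-region detection in
    mitochondrial DNA, and UPGMA phylogenies with bootstrap support.
    Includes seeded simulators for plastomes, diverged lineages, mitogenomes
    with plastid-derived insertions, and error-model reads with full ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    GenomicRanges,
    IRanges,
    Rcpp,
    rtracklayer,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
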