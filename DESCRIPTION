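Package: hitiquant
Title: Quantification of Homology-Independent Targeted Integration from Amplicon and Capture Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and evaluating CRISPR/Cas9 homology-independent
    targeted integration (HITI) experiments from sequencing reads. Builds
    promoterless donor cassettes flanked by inverted gRNA target sites and
    predicts post-integration junctions and re-cleavage; simulates edited-allele
    populations and amplicon, junction and capture-style read sets with ground
    truth; aligns reads with an internal affine-gap local aligner emitting
    CIGAR strings with soft clips; quantifies INDELs in a window around the
    cleavage site, estimates the integrated-allele fraction by dual-amplicon
    read classification, classifies junction precision with per-tissue
    frequency thresholds, detects donor and vector integration sites from
    split reads, and predicts genotype frequencies under Hardy-Weinberg
    assumptions.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
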