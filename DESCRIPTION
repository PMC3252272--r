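Package: mirduplex
Title: Bulge-Aware Plant miRNA-Target Duplex Alignment and Small RNA
    Variant Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Aligns plant microRNAs to candidate target sites allowing
    mismatches, G:U wobbles and asymmetric bulges, scores the pairs with
    an empirical plant complementarity penalty, and evaluates duplex
    hybridization free energies with an embedded Turner 2004
    nearest-neighbor parameter set.  Scans spliced transcript models for
    target sites (including sites formed across exon junctions), maps
    predicted cleavage coordinates opposite miRNA positions 10-11,
    prioritizes candidate targets by expression up-regulation in miRNA
    pathway mutants, profiles per-position sequence variation within
    miRNA families, and quantifies the relative abundance of miRNA
    sequence variants in small RNA sequencing libraries.  Includes a
    synthetic data generator that plants target sites, fold-change
    matrices and read libraries with recorded ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    jsonlite,
    optparse,
    Rcpp,
    rtracklayer,
    S4Vectors,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
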