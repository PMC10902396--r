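Package: epseq
Title: Expression and Activity Fitness Estimation for Enzyme Proximity
    Sequencing
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for enzyme proximity sequencing (EP-Seq), a FACS
    sort-seq deep mutational scanning assay that measures expression
    (folding stability proxy) and catalytic activity phenotypes of
    enzyme variant libraries displayed on yeast. Builds UMI-to-variant
    look-up tables from long-read derived records with quality filtering
    and conflict resolution, extracts and tags UMIs from per-bin short
    reads, converts read counts to sorted-cell numbers and
    bin-median-weighted fluorescence scores, computes log2 fitness with
    replicate consensus, deconvolutes activity from expression via
    normalized activity scores, extracts per-residue structural features
    (Shrake-Rupley solvent accessibility, B-factors, cofactor, interface
    and active-site distances) from PDB files, and joins fitness with
    structure for landscape analysis. Includes a synthetic sort-seq
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    Biostrings,
    bio3d,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
biocViews: Sequencing, Proteomics, StructuralPrediction, Software
RoxygenNote: 7.3.3
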