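Package: tcrfp
Title: ElectroShape-5D Fingerprints for T-Cell Receptor Repertoire Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Converts paired alpha/beta T-cell receptor (TCR) 3D structures
    into fixed-length 18-value ElectroShape-5D fingerprints computed over the
    six complementarity-determining region (CDR) loops, and compares them with
    a Manhattan-distance based similarity score. Includes distance-based
    quality-control filters for structural models calibrated on reference
    structures (mean +/- 4 SD over conserved-residue distances), a normalized
    BLOSUM62 sequence comparator, a logistic-regression combiner of shape and
    sequence similarity, a genetic algorithm optimizing universal centroid
    positions and property weights, specificity-pairing evaluation statistics
    (peptide identity, sequence recapitulation, rank/threshold tables, ROC/AUC
    with cross-validation, UPGMA clustering), and a synthetic TCR-structure
    generator so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
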