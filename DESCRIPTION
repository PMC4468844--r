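Package: beadphase
Title: Single-Molecule Phasing by Massively Parallel Bead Barcoding
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Author: Package Author [aut, cre]
Maintainer: Package Author <author@example.org>
Description: Simulation and analysis of two-stage emulsion bead-barcoding
    experiments for phasing short amplicons to single DNA molecules.
    Provides closed-form Poisson droplet/bead loading expectations, a
    seeded simulator of barcoded-bead libraries and phasing/sorting runs
    with full ground truth, mismatch-tolerant iterative barcode
    clustering, per-target amplicon consensus calling with clonality
    classification, k-mer containment taxonomic assignment against a
    small reference set, and the phasing statistics (observed, shuffled
    null, and chance-corrected phasing rates, dominant-species removal,
    hit-list overlap reduction, and sequencing-depth subsampling).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
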