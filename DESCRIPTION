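Package: shiftref
Title: Coordinate-Based Correction and Validation of Protein NMR Chemical
    Shifts
Version: 0.1.0
Authors@R:
    person("shiftref", "maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Detects and corrects per-entry referencing offsets in protein
    NMR chemical shift lists using the matching 3D coordinates. Shifts are
    classified by atom type, secondary structure state and per-atom solvent
    accessible surface area bin; each class carries a Gaussian reference
    distribution, and a conjugate Bayesian posterior under a flat prior
    yields one correction factor per nucleus group (H, N, aliphatic,
    aromatic and proton-less carbons) together with its uncertainty.
    Corrections smaller than three times their uncertainty are discarded,
    and per-atom Z-scores flag individual outlier shifts. Includes
    Shrake-Rupley surface areas, hydrogen-bond based secondary structure
    assignment, Needleman-Wunsch sequence mapping, reference-database
    construction with iterative self-consistent correction, synthetic data
    generators, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    Biostrings
Config/testthat/edition: 3
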