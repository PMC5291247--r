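Package: spindock
Title: Integrative Rigid-Body Docking with PELDOR and Cross-Linking Distance Restraints
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for deriving structural models of protein complexes from
    sparse distance restraints. Simulates nitroxide spin-label ensembles
    (monofunctional R1 by accessible-volume sampling, bifunctional Rx2
    bridging two cysteines), converts pulsed electron-electron double
    resonance (PELDOR/DEER) dipolar time traces to distance distributions by
    background correction and non-negative Tikhonov regularization,
    identifies isotope-coded (d0/d4) cross-linked peptide pairs from MS/MS
    peak lists with decoy-based false discovery rate control, and docks two
    rigid bodies against the resulting restraints from randomized starting
    orientations with acceptance, ensemble averaging, validation and
    tetramer extrapolation. Includes a synthetic-data module generating toy
    rigid bodies, dipolar traces and cross-linked spectra with known ground
    truth, and small mass-accounting helpers for cross-linker adduct counts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
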