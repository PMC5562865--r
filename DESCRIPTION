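Package: afmunfold
Title: Single-Molecule AFM Unfolding Analysis for Multidomain Adhesion Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis of single-molecule atomic force microscopy (smAFM)
    force-extension curves of multidomain proteins, built around the neuronal
    cell adhesion molecule contactin-4 (CNTN4). Provides worm-like-chain (WLC)
    evaluation, inversion and per-branch contour-length fitting; a quasi-static
    constant-velocity simulator that synthesizes saw-tooth retraction curves
    with ground truth (disulfide-clamped IgC2 and fully extensible FnIII
    unfolding events, unfolding intermediates, partial-domain events and a
    low-force horseshoe-opening plateau); the inference pipeline from raw
    curve to per-event contour-length increments and rupture forces; Gaussian
    mixture decomposition of increment and force populations with domain-class
    assignment and detectors for characteristic spectral features; and an
    anisotropic-network-model mechanical stiffness module computing effective
    spring constants between residue pairs from C-alpha coordinates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    mclust,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    MASS,
    jsonlite,
    ggplot2,
    withr
Config/testthat/edition: 3
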