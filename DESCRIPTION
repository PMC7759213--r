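Package: fretquant
Title: Quantification of Receptor Association by Flow and Image FRET
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for quantifying receptor dimerization by sensitized-emission
    Forster resonance energy transfer (FRET). Implements per-cell normalized
    FRET (NFRET) for flow cytometry with spillover estimation from
    single-colour controls, linear compensation, density and singlet gating,
    and control-based calibration; pixel-wise three-channel FRET for
    microscopy fields with autofluorescence thresholding, saturated-pixel
    removal, bleed-through correction and NFRET maps; rainbow-bead
    fluorescence calibration (MEFL), dual-luciferase and western-blot
    normalization, fold differences with first-order error propagation, and
    an ectodomain-distance regression. A synthetic-data generator emulates
    the full measurement process (lognormal co-expression, ligand-dose
    dependent dimerization, distance-dependent FRET efficiency, spectral
    bleed-through, autofluorescence, saturation, doublets and calibration
    beads) so every stage can be verified against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    MASS,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    tidyr,
    tiff
Config/testthat/edition: 3
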