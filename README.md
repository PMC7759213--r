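# fretquant

Quantification of receptor association by flow-cytometric and image-based
sensitized-emission FRET, with the calibration and normalization machinery
that surrounds such assays.

## The problem

Synthetic (and natural) receptors often signal through ligand-induced
dimerization of two transmembrane chains. A direct way to measure whether two
chains associate — with or without ligand — is Förster resonance energy
transfer (FRET): tag one chain with a donor fluorophore (e.g. mCerulean) and
the other with an acceptor (e.g. mVenus); energy transfer occurs only when
the two sit within roughly 10 nm. Measured per cell on a flow cytometer,
the sensitized acceptor emission reports receptor association at single-cell
resolution over thousands of cells — but only after correcting for spectral
bleed-through and for the enormous cell-to-cell variation in expression.

`fretquant` implements that workflow end to end:

* **Flow FRET** — spillover estimation from single-colour controls,
  linear compensation, density (FSC-A/SSC-A) and singlet (FSC-A/FSC-H)
  gating, quantile-based positivity gates with a stated false-inclusion
  rate, and the per-cell normalized FRET metric

  $$NFRET_i = \frac{\text{comp AmCyan}_i}{\sqrt{\text{comp Pacific Blue}_i
  \times \text{comp FITC}_i}},$$

  optionally calibrated linearly between a non-interacting negative control
  (→ 0) and a covalent donor–acceptor fusion (→ 1).
* **Image FRET** — pixel-wise three-channel (DD/AA/DA) analysis of
  microscopy fields: autofluorescence thresholds at the 99.9th percentile of
  vector-only pixels, saturated-pixel removal, bleed-through parameters
  $a = \overline{I_{DA}/I_{AA}}$, $b = \overline{I_{DD}/I_{AA}}$
  (acceptor-only), $c = \overline{I_{AA}/I_{DD}}$,
  $d = \overline{I_{DA}/I_{DD}}$ (donor-only), the corrected FRET intensity
  $F_c = I_{DA} - a(I_{AA} - cI_{DD}) - d(I_{DD} - bI_{AA})$ (a literal
  "flat" variant is also provided), and pixel-wise
  $NFRET = F_c/\sqrt{I_{AA} I_{DD}}$ with deterministic heatmap rendering.
* **Calibration & normalization** — rainbow-bead MEFL calibration
  (origin-constrained regression of MFI on reference values, automated
  subpopulation identification), dual-luciferase plate normalization,
  western-blot percent-of-total expression normalization across exposures,
  fold differences with first-order (delta-method) error propagation, and
  the regression of NFRET fold difference on ectodomain C-terminal distance.
* **A synthetic-data generator** that emulates the measurement process with
  known ground truth — lognormal co-expression, dose-dependent dimerization,
  distance-dependent Förster efficiency, spectral mixing, autofluorescence,
  detector saturation, flow doublets and multi-subpopulation calibration
  beads — so every stage of the pipeline is verifiable without real data.

All user-facing functions take data frames (or the package's light field /
model objects) and return tibbles; fitted objects have `tidy()` / `glance()`
methods and `autoplot()` / `plot_*()` visualizations.

## Worked example

Simulate a rapalog-style titration experiment (2,500 cells per sample) with
its full control set, run the flow pipeline and compute the ligand-induced
fold difference:

```r
library(fretquant)

cfg_veh <- sim_config(seed = 7, n_cells = 2500)                    # vehicle
cfg_lig <- sim_config(seed = 7, n_cells = 2500, ligand_dose = 100) # 100 nM
controls <- simulate_control_set(cfg_veh)

veh <- analyze_flow_fret(simulate_flow_sample(cfg_veh), controls,
                         calibrate = TRUE)
lig <- analyze_flow_fret(simulate_flow_sample(cfg_lig), controls,
                         calibrate = TRUE)
lig
#> <flow_fret_analysis> 1303 cells | mean NFRET 0.2725 | calibrated 0.336

fold_difference(lig$mean_nfret, veh$mean_nfret)
#> # A tibble: 1 × 3
#>    fold fold_se fold_defined
#>   <dbl>   <dbl> <lgl>
#> 1  8.48       0 TRUE

lig$model
#> <spillover_model> (estimated)
#>            Pacific Blue   FITC AmCyan   APC
#> donor            1.0000 0.0485 0.3930 1e-04
#> acceptor         0.0194 1.0000 0.1495 0e+00
#> sensitized       0.0000 0.0000 1.0000 0e+00
#> marker           0.0000 0.0000 0.0000 1e+00
```

The analysis gated 1,303 single, transfected, donor+/acceptor+ cells; the
spillover matrix estimated from the single-colour controls recovers the
generator's true bleed-through (a, b, c, d) = (0.15, 0.02, 0.05, 0.40) to
within ~2%, and 100 nM ligand raises mean NFRET 8.5-fold over vehicle —
the dimerization readout the assay is built to detect.

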