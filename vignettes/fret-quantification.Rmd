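---
title: "Quantifying receptor association by flow and image FRET"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying receptor association by flow and image FRET}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fretquant)
```

## The measurement and its model

Ligand-induced dimerization of two-chain receptors can be read out by
Förster resonance energy transfer: the intracellular domains of the two
chains are replaced with a donor (mCerulean) and an acceptor (mVenus)
fluorophore, and energy transfer — effective only below roughly 10 nm of
separation — reports whether the chains associate. On a cytometer the three
relevant signals are the donor channel (Pacific Blue; 405 nm excitation,
450/50 emission), the acceptor channel (FITC; 488 nm, 530/30) and the FRET
channel (AmCyan; 405 nm excitation but 530/30 emission — donor excitation,
acceptor emission). A constitutive far-red marker (APC channel) identifies
transfected cells. On a confocal microscope the same three signals are the
DD, AA and DA images of each field of view.

Raw FRET-channel intensity is useless by itself: it scales with how much
donor and acceptor a given cell happens to express, and transient
transfection spreads expression over orders of magnitude. The package
therefore centres on the *normalized* FRET metric, computed per cell on
compensated intensities:

$$NFRET_i = \frac{\text{comp AmCyan}_i}
{\sqrt{\text{comp Pacific Blue}_i \times \text{comp FITC}_i}}$$

which is invariant to uniform rescaling of a cell's fluorescence (the test
suite checks this to 1e-12). Because NFRET is still an arbitrary-unit
quantity, it can be calibrated linearly between two controls measured in the
same experiment — a co-expressed but non-interacting donor/acceptor pair
(calibrated NFRET 0) and a covalent donor–acceptor fusion (calibrated
NFRET 1):

$$NFRET_{cal} = \frac{NFRET - NFRET_{neg}}{NFRET_{pos} - NFRET_{neg}}.$$

The ligand effect on association is summarized as the *fold difference*:
mean NFRET with ligand divided by mean NFRET with vehicle, with standard
error propagated to first order,
$SE_F = F\sqrt{(SE_L/\mu_L)^2 + (SE_V/\mu_V)^2}$. The same delta-method
propagation is used for every ratio and linear scaling in the package; a
10,000-draw parametric bootstrap in the test suite agrees with it to a few
percent at the coefficients of variation (≤ 0.2) these assays produce.

## The flow workflow

`analyze_flow_fret()` chains the steps in their fixed order:

1. **Cell gate.** The manually drawn FSC-A/SSC-A gate of interactive
   software is replaced by a density gate: a 2-D kernel density estimate
   keeps the densest `keep_fraction` (default 0.75) of events. An explicit
   subset can always be supplied instead.
2. **Singlet gate.** Doublets double forward-scatter area but not height;
   events are kept when FSC-A/FSC-H lies within ±15% (default) of the
   population median ratio. On simulated data with labelled doublets this
   removes ≥ 95% of them while retaining ≥ 99% of singlets.
3. **Spillover estimation and compensation.** For each single-colour
   control, the coefficient into every off-channel is the origin-constrained
   least-squares slope of off-channel vs primary-channel intensity over the
   autofluorescence-subtracted positive events; the per-event channel vector
   is multiplied by the inverse of this matrix. Negative compensated values
   are retained — discarding them would bias population statistics.
4. **Positivity gates.** Each threshold is the `(1 - rate)` linear-
   interpolation quantile of the relevant negative population (vector-only
   for the transfection marker, each single-colour control for the opposite
   fluorophore), so gating strictly above it re-includes at most `rate`
   (default 1%) of that control.
5. **NFRET.** Cells whose compensated donor × acceptor product is not
   strictly positive have no defined NFRET; they are flagged and excluded
   from every summary rather than clamped.

Fold differences across biological replicates average per-replicate means
first (`summarize_sample()`); pooling all cells before averaging is
available via `pool_cells = TRUE`, since which order an exported workspace
used is ambiguous in practice. Replicate-mean-first is the default.

## The image workflow

`analyze_image_fret()` mirrors the released image-processing approach:

1. Per-channel autofluorescence thresholds are the 99.9th percentile of
   pixels pooled across the vector-only fields (pooled pixels, not averaged
   per-field statistics; linear-interpolation quantiles).
2. Pixels at or below the threshold are zeroed; pixels at the saturation
   value in any channel are removed outright and excluded from every
   downstream average. Zeroing *ties* at the threshold keeps the surviving
   background fraction within the nominal 0.1% even for integer-quantized
   images, where a tied mass can sit exactly at the percentile value; for
   continuous intensities the convention is indistinguishable from a strict
   inequality.
3. Bleed-through parameters are pixel-ratio means over the masked
   single-colour fields: from acceptor-only fields $a = I_{DA}/I_{AA}$ and
   $b = I_{DD}/I_{AA}$; from donor-only fields $c = I_{AA}/I_{DD}$ and
   $d = I_{DA}/I_{DD}$; zero-denominator pixels are excluded.
4. The corrected FRET intensity defaults to the nested form
   $F_c = I_{DA} - a(I_{AA} - cI_{DD}) - d(I_{DD} - bI_{AA})$, in which each
   single-colour image is cleaned of the other fluorophore's spill before
   being scaled out of the FRET channel. The flat form
   $F_c = I_{DA} - aI_{AA} - cI_{DD} - dI_{DD} - bI_{AA}$ is available as an
   explicit variant, and the variant used is recorded on every output. The
   two coincide exactly whenever $b \cdot c = 0$. Note that against a truly
   linear mixing process the nested form is itself a first-order correction:
   the exact unmix would divide by $(1 - bc)$, a 0.1% effect at this
   package's default coefficients — the tests document both the exact
   ($bc = 0$) and the $O(bc)$ behaviour.
5. $NFRET = F_c/\sqrt{I_{AA} I_{DD}}$ per pixel where defined. The sample
   mean pools defined pixels across fields (equivalently, the
   pixel-count-weighted mean of field means); the unweighted mean of field
   means is reported alongside, since the two summaries differ when fields
   carry unequal cell numbers. Any number of fields ≥ 1 is accepted and the
   count is logged in the summary.

When $b = c = 0$ the image correction is algebraically identical to flow
compensation restricted to the three FRET channels, and the test suite
verifies that running the defined pixels of a synthetic field through the
flow path reproduces the pixel NFRET values to 1e-9. Heatmaps are rendered
with `render_maps()` straight to PNG with a fixed colour scale and a
distinct flat colour for masked pixels, so identical inputs give
byte-identical files; `autoplot()` methods cover interactive use.

## Calibration and normalization

* **Beads.** Rainbow-bead subpopulations are identified by 1-D k-means on
  log intensity with sorted-quantile initialization (deterministic;
  `k = 6` for RCP-type, `9` for URCP-type reagents) — the manual two-channel
  gating of bead clouds automated. The calibration is an origin-constrained
  regression of measured MFI *on* the reference MEFL values
  (slope = Σxy/Σx², a.u. per MEFL); conversion subtracts cell
  autofluorescence first, then divides by the slope. The inverse regression
  orientation is mathematically different and deliberately not used.
* **Dual-luciferase plates.** Technical replicates are averaged per well;
  the mean of the vector-only wells is subtracted per readout; Firefly is
  divided by Renilla; and all quotients are scaled so the reporter-only
  condition mean is exactly 1 a.u. Wells with nonpositive
  background-subtracted Renilla are flagged invalid instead of producing
  infinities.
* **Western blots.** Receptor and loading-control (NanoLuciferase) bands
  are each expressed as percent of their total over the usable lanes of an
  exposure — percent-of-total cancels exposure-to-exposure gain exactly —
  averaged across the exposures in which the lane is usable
  (non-detectable/saturated flags are caller-supplied; no densitometric
  auto-flagging), ratioed, and referenced to a designated internal-control
  lane. The reciprocal is reported as a suggested plasmid-dose scaling. The
  cross-blot comparison is implemented as simple division by the control
  lane; no additional renormalization across blots is applied.
* **Distance regression.** `distance_regression()` fits ordinary least
  squares of NFRET fold difference on the ectodomain C-terminal distance
  (user-supplied Angstrom values from crystal structures), returning slope,
  intercept, R² and the two-tailed slope p-value.

## The synthetic generator

`sim_config()` fixes the generative model every verification runs against.
Per cell, a lognormal expression scale (meanlog `log(5000)`, sdlog 0.8 —
transient transfection spanning about two orders of magnitude on an 18-bit
cytometer) sets donor, acceptor (1.5× brighter, as mVenus is) and marker
amounts. A dose-dependent fraction
$f = f_{veh} + (f_{max} - f_{veh})L/(L + EC_{50})$ of the limiting chain
forms complexes — mass-action-lite, $C = f\min(D, A)$, with no stoichiometry
model — whose FRET efficiency follows the Förster sixth-power relation
$E = 1/(1 + (r/R_0)^6)$ with $R_0$ = 50 Å. The Förster form is a modelling
choice: any strictly decreasing efficiency–distance map would serve, and
this one is physically standard. Transferred intensity is moved from the
donor source into the sensitized source, so donor quenching is bookkept
exactly (donor + sensitized source = total donor amount, a tested
invariant).

Default rates and fractions: vehicle dimer fraction 0.05, maximum 0.60,
EC50 10 nM (so a 100 nM dose is near-saturating), fusion-control efficiency
0.6, doublet fraction 0.05, bleed-through (a, b, c, d) =
(0.15, 0.02, 0.05, 0.40), multiplicative lognormal noise with CV 0.1 per
channel, flow autofluorescence lognormal(meanlog log 50, sdlog 0.4), and a
confocal background of lognormal(meanlog log 2, sdlog 0.5) per pixel —
photon-counting hybrid detectors contribute only a few counts of offset,
and a low additive background also keeps the additive bias on the smallest
pixel-ratio coefficient ($b$) an order of magnitude below the estimator's
sampling error. Fluorophore brightness ratios and detector gains are not
published quantities; these defaults are documented choices, not fitted
values. Doublets are pairwise event merges: area and fluorescence sum,
height follows the larger cell, which is exactly the structure the singlet
gate removes. Poisson shot noise is omitted (intensities are arbitrary
units, not photon counts).

Image fields place non-overlapping flat disks (default radius 10 px, 25
cells on 256×256 fields) on the background; there is no PSF, illumination
falloff, z-structure or cell segmentation — the pixel workflow averages
over pixels, not cells, so none is needed. Pixels are clipped at
$2^{16}-1$ and rounded to integers; `quantize = FALSE` disables rounding
for exact round-trip checks, since integer rounding would otherwise mask
1e-9-level agreement. Every sample draws from an explicit seed in its
config (controls and multi-field sets use fixed offsets from it); no global
RNG state is consumed.

What passing tests on this generator do **not** show: robustness to
spectral-overlap nonlinearity at detector extremes, autofluorescence that
correlates with cell size, optical artefacts, or FCS-file idiosyncrasies —
real acquisitions should still be inspected with the usual plots
(`plot_nfret()`, `autoplot()`).

## Numerical choices and problem sizes

Quantiles are type-7 (linear interpolation between order statistics)
throughout. Compensation errors on singular matrices rather than
pseudo-inverting. NFRET and pixel NFRET are undefined (flagged `NA`, never
clamped) where the donor–acceptor product is nonpositive. k-means
initialization is deterministic, so bead identification is reproducible.
The test and acceptance runs use 2,000–2,500 cells per flow sample —
matching the few-thousand-cell populations such assays typically gate —
10,000 events where a false-inclusion rate is being measured, and ten
256×256 fields per imaging control; the distance-trend check repeats a
four-system, two-arm pipeline twenty times under different seeds and
expects a negative fitted slope in at least 95% of them.

## Limitations

Bleed-through correction is linear; strongly saturating detectors violate
it (saturated pixels/events are removed, but near-saturation nonlinearity
is not modelled). The density cell gate is a convenience default, not a
replacement for inspecting scatter plots on unfamiliar samples. Western
quantification takes band intensities as input — gel densitometry is out
of scope. Hypothesis testing (ANOVA families, multiple-testing correction)
is left to the standard tools.
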