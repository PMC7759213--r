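#' Spillover/bleed-through mixing matrix
#'
#' Builds the source-by-channel mixing matrix used both as simulation ground
#' truth and as a manually specified compensation model. Rows are signal
#' sources (donor, acceptor, sensitized emission, marker), columns are the
#' four fluorescence channels; diagonal entries (each source into its primary
#' channel) are fixed at 1. The four off-diagonal coefficients follow the
#' three-cube bleed-through convention:
#' \describe{
#'   \item{a}{acceptor into the FRET channel (AmCyan / DA)}
#'   \item{b}{acceptor into the donor channel (Pacific Blue / DD)}
#'   \item{c}{donor into the acceptor channel (FITC / AA)}
#'   \item{d}{donor into the FRET channel (AmCyan / DA)}
#' }
#'
#' @param a,b,c,d Bleed-through fractions, each in `[0, 1)`.
#' @return A `spillover_model` object.
#' @export
#' @examples
#' spillover_matrix(a = 0.15, b = 0.02, c = 0.05, d = 0.40)
spillover_matrix <- function(a = 0, b = 0, c = 0, d = 0) {
  coefs <- c(a = a, b = b, c = c, d = d)
  if (any(!is.finite(coefs)) || any(coefs < 0) || any(coefs >= 1)) {
    abort("bleed-through coefficients a, b, c, d must lie in [0, 1)")
  }
  m <- diag(4)
  dimnames(m) <- list(.sources, .fluor_channels)
  m["donor", "FITC"] <- c
  m["donor", "AmCyan"] <- d
  m["acceptor", "Pacific Blue"] <- b
  m["acceptor", "AmCyan"] <- a
  new_spillover_model(m, coefficients = coefs, source = "specified")
}

new_spillover_model <- function(matrix, coefficients = NULL, source = "estimated",
                                details = NULL) {
  structure(
    list(
      matrix = matrix,
      coefficients = coefficients,
      source = source,
      details = details
    ),
    class = "spillover_model"
  )
}

#' @export
print.spillover_model <- function(x, ...) {
  cat("<spillover_model> (", x$source, ")\n", sep = "")
  print(round(x$matrix, 4))
  invisible(x)
}

#' @describeIn spillover_matrix Long-format coefficients of a spillover model.
#' @param x A `spillover_model`.
#' @param ... Unused.
#' @export
tidy.spillover_model <- function(x, ...) {
  m <- x$matrix
  tibble(
    source = rep(rownames(m), times = ncol(m)),
    channel = rep(colnames(m), each = nrow(m)),
    coefficient = as.vector(m)
  )
}

#' Simulation configuration for the synthetic FRET measurement process
#'
#' Collects every parameter of the generative model: per-cell lognormal
#' expression heterogeneity, transfection probability, fluorophore brightness
#' rates, ligand-dose-dependent dimerization (hyperbolic dose response),
#' distance-dependent Forster efficiency, spectral mixing, autofluorescence,
#' multiplicative measurement noise, detector saturation, doublet formation,
#' and the microscopy field geometry. Defaults emulate a transient
#' co-transfection read on an 18-bit cytometer and a 16-bit photon-counting
#' confocal; see the package vignette for the rationale behind each value.
#'
#' @param seed Integer seed; all generator randomness derives from it.
#' @param n_cells Number of cells per simulated flow sample.
#' @param p_transfected Probability that a cell is transfected.
#' @param expr_mu,expr_sigma Meanlog/sdlog of the per-cell expression scale.
#' @param donor_rate,acceptor_rate,marker_rate Brightness per expression unit
#'   for donor, acceptor and transfection marker.
#' @param dimer_fraction_vehicle,dimer_fraction_max Fraction of the limiting
#'   chain in complexes without ligand and at saturating ligand.
#' @param ec50 Ligand dose (nM) at half-maximal induction.
#' @param ligand_dose Applied ligand dose (nM); 0 is the vehicle arm.
#' @param ecd_distance Donor-acceptor separation (Angstrom) imposed by the
#'   ligand-bound ectodomains.
#' @param forster_radius Forster radius R0 (Angstrom) of the fluorophore pair.
#' @param e_fusion FRET efficiency of the covalent donor-acceptor fusion used
#'   as the positive control.
#' @param mixing A `spillover_model` holding the true bleed-through.
#' @param autofl_mu,autofl_sigma Lognormal autofluorescence parameters per
#'   flow channel (`-Inf` mean gives zero autofluorescence).
#' @param bg_mu,bg_sigma Lognormal background parameters per microscopy
#'   channel pixel.
#' @param noise_cv Coefficient of variation of multiplicative measurement
#'   noise applied per channel (and per pixel for images).
#' @param doublet_fraction Fraction of flow events that are two merged cells
#'   (summed area/fluorescence, height from the larger cell).
#' @param saturation_value Flow detector saturation (a.u.).
#' @param image_shape Integer vector `c(rows, cols)` of a microscopy field.
#' @param cell_radius_px Radius of a simulated cell disk, pixels.
#' @param n_cells_field Cells placed per microscopy field.
#' @param image_bit_depth Bit depth of stored images; saturation is
#'   `2^image_bit_depth - 1`.
#' @param quantize Round image pixels to integers (as acquired data would
#'   be)? Disable for exact round-trip checks.
#' @return A validated `sim_config` object (a named list).
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, n_cells = 500, ligand_dose = 100)
#' dimer_fraction(cfg)
sim_config <- function(seed = 1L,
                       n_cells = 5000L,
                       p_transfected = 0.7,
                       expr_mu = log(5000),
                       expr_sigma = 0.8,
                       donor_rate = 1,
                       acceptor_rate = 1.5,
                       marker_rate = 0.5,
                       dimer_fraction_vehicle = 0.05,
                       dimer_fraction_max = 0.6,
                       ec50 = 10,
                       ligand_dose = 0,
                       ecd_distance = 50,
                       forster_radius = 50,
                       e_fusion = 0.6,
                       mixing = spillover_matrix(a = 0.15, b = 0.02,
                                                 c = 0.05, d = 0.40),
                       autofl_mu = log(50),
                       autofl_sigma = 0.4,
                       bg_mu = log(2),
                       bg_sigma = 0.5,
                       noise_cv = 0.1,
                       doublet_fraction = 0.05,
                       saturation_value = 2^18 - 1,
                       image_shape = c(256L, 256L),
                       cell_radius_px = 10,
                       n_cells_field = 25L,
                       image_bit_depth = 16L,
                       quantize = TRUE) {
  cfg <- structure(
    list(
      seed = as.integer(seed), n_cells = as.integer(n_cells),
      p_transfected = p_transfected,
      expr_mu = expr_mu, expr_sigma = expr_sigma,
      donor_rate = donor_rate, acceptor_rate = acceptor_rate,
      marker_rate = marker_rate,
      dimer_fraction_vehicle = dimer_fraction_vehicle,
      dimer_fraction_max = dimer_fraction_max,
      ec50 = ec50, ligand_dose = ligand_dose,
      ecd_distance = ecd_distance, forster_radius = forster_radius,
      e_fusion = e_fusion, mixing = mixing,
      autofl_mu = autofl_mu, autofl_sigma = autofl_sigma,
      bg_mu = bg_mu, bg_sigma = bg_sigma,
      noise_cv = noise_cv, doublet_fraction = doublet_fraction,
      saturation_value = saturation_value,
      image_shape = as.integer(image_shape),
      cell_radius_px = cell_radius_px,
      n_cells_field = as.integer(n_cells_field),
      image_bit_depth = as.integer(image_bit_depth),
      quantize = isTRUE(quantize)
    ),
    class = "sim_config"
  )
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  fracs <- c(
    p_transfected = cfg$p_transfected,
    dimer_fraction_vehicle = cfg$dimer_fraction_vehicle,
    dimer_fraction_max = cfg$dimer_fraction_max,
    e_fusion = cfg$e_fusion,
    doublet_fraction = cfg$doublet_fraction
  )
  if (any(fracs < 0 | fracs > 1)) {
    abort(paste0(
      "fractions must lie in [0, 1]: ",
      paste(names(fracs)[fracs < 0 | fracs > 1], collapse = ", ")
    ))
  }
  nonneg <- c(
    cfg$donor_rate, cfg$acceptor_rate, cfg$marker_rate,
    cfg$ecd_distance, cfg$ligand_dose, cfg$noise_cv, cfg$cell_radius_px
  )
  if (any(nonneg < 0)) {
    abort("rates, radii, doses and noise_cv must be nonnegative")
  }
  if (cfg$ec50 <= 0) abort("ec50 must be positive")
  if (cfg$forster_radius <= 0) abort("forster_radius must be positive")
  if (cfg$n_cells < 0) abort("n_cells must be nonnegative")
  if (cfg$saturation_value <= exp(cfg$autofl_mu)) {
    abort("saturation_value must exceed the median autofluorescence")
  }
  if (!inherits(cfg$mixing, "spillover_model")) {
    abort("mixing must be a spillover_model (see spillover_matrix())")
  }
  if (length(cfg$image_shape) != 2 || any(cfg$image_shape < 1)) {
    abort("image_shape must be two positive integers")
  }
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> seed", x$seed, "|", x$n_cells, "cells |",
      "dose", x$ligand_dose, "nM | distance", x$ecd_distance, "A\n")
  invisible(x)
}
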