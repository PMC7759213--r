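#' Ligand-dose-dependent dimer fraction
#'
#' Hyperbolic (one-site) dose response for the fraction of the limiting
#' receptor chain that is in complexes:
#' \eqn{f = f_{veh} + (f_{max} - f_{veh}) \, L / (L + EC_{50})}.
#'
#' @param config A [sim_config()].
#' @param dose Ligand dose in nM; defaults to `config$ligand_dose`.
#' @return Dimer fraction in `[f_veh, f_max]`.
#' @export
#' @examples
#' cfg <- sim_config(dimer_fraction_vehicle = 0.05, dimer_fraction_max = 0.85,
#'                   ec50 = 10)
#' dimer_fraction(cfg, dose = 10) # halfway: 0.45
dimer_fraction <- function(config, dose = config$ligand_dose) {
  if (any(dose < 0)) abort("ligand dose must be nonnegative")
  f_veh <- config$dimer_fraction_vehicle
  f_max <- config$dimer_fraction_max
  f_veh + (f_max - f_veh) * dose / (dose + config$ec50)
}

#' Forster FRET efficiency at a given donor-acceptor distance
#'
#' Sixth-power Forster relation \eqn{E = 1 / (1 + (r/R_0)^6)}: efficiency is
#' 1 at contact, 1/2 at the Forster radius, and falls steeply beyond it
#' (FRET is effectively confined to separations below ~10 nm).
#'
#' @param distance Donor-acceptor separation, Angstrom.
#' @param forster_radius Forster radius R0, Angstrom.
#' @return Efficiency in `[0, 1]`, strictly decreasing in distance.
#' @export
#' @examples
#' fret_efficiency(50, 50) # 0.5
fret_efficiency <- function(distance, forster_radius) {
  if (any(distance < 0)) abort("distance must be nonnegative")
  if (any(forster_radius <= 0)) abort("forster_radius must be positive")
  1 / (1 + (distance / forster_radius)^6)
}

# Per-cell ground-truth amounts shared by the flow and image generators.
# Returns donor/acceptor/marker amounts, complexes and the efficiency.
draw_cell_truth <- function(config, n, dimer_fraction = NULL,
                            efficiency = NULL) {
  s <- rlnorm(n, config$expr_mu, config$expr_sigma)
  transfected <- runif(n) < config$p_transfected
  d_amt <- config$donor_rate * s * transfected
  a_amt <- config$acceptor_rate * s * transfected
  r_amt <- config$marker_rate * s * transfected
  f <- dimer_fraction %||% dimer_fraction(config)
  e <- efficiency %||%
    fret_efficiency(config$ecd_distance, config$forster_radius)
  c_amt <- f * pmin(d_amt, a_amt)
  tibble(
    donor_amount = d_amt,
    acceptor_amount = a_amt,
    marker_amount = r_amt,
    complex_amount = c_amt,
    fret_efficiency = e,
    transfected = transfected
  )
}

# Map per-cell amounts to the four clean channel sources. Donor emission is
# quenched by the transferred fraction, so donor source + sensitized source
# conserves the total donor amount.
source_matrix <- function(truth) {
  sens <- truth$fret_efficiency * truth$complex_amount
  cbind(
    donor = truth$donor_amount - sens,
    acceptor = truth$acceptor_amount,
    sensitized = sens,
    marker = truth$marker_amount
  )
}

#' Simulate one flow-cytometry sample with known ground truth
#'
#' Generates a per-event table in the FRET panel channels. Per cell, a
#' lognormal expression scale sets donor/acceptor/marker amounts; a
#' dose-dependent fraction of the limiting chain forms complexes whose
#' distance-dependent Forster efficiency moves donor emission into the
#' sensitized (AmCyan) source; sources are mixed through the configured
#' spillover matrix, autofluorescence is added, multiplicative lognormal
#' noise applied, and channels clipped at the detector saturation. Scatter
#' channels carry singlet/doublet structure: a configurable fraction of
#' events are two merged cells, which doubles FSC-A (and sums fluorescence)
#' but leaves FSC-H at the larger cell's height.
#'
#' @param config A [sim_config()].
#' @param sample_id,replicate Metadata recorded on the events.
#' @param treatment Arm label; defaults to `"ligand"` when
#'   `config$ligand_dose > 0`, else `"vehicle"`.
#' @param dimer_fraction,efficiency Optional overrides of the dose-derived
#'   dimer fraction and distance-derived FRET efficiency (used for the
#'   fusion-protein positive control).
#' @return A list of class `flow_sim` with `events` (tibble: scatter and
#'   fluorescence channels plus metadata) and `truth` (tibble of per-cell
#'   ground truth, including doublet labels).
#' @export
#' @examples
#' sim <- simulate_flow_sample(sim_config(seed = 7, n_cells = 100))
#' head(sim$events)
simulate_flow_sample <- function(config,
                                 sample_id = "sample",
                                 treatment = NULL,
                                 replicate = 1L,
                                 dimer_fraction = NULL,
                                 efficiency = NULL) {
  treatment <- treatment %||%
    (if (config$ligand_dose > 0) "ligand" else "vehicle")
  n <- config$n_cells
  if (n == 0) {
    empty <- tibble(
      `FSC-A` = double(), `FSC-H` = double(), `SSC-A` = double(),
      `Pacific Blue` = double(), FITC = double(), AmCyan = double(),
      APC = double(),
      sample = character(), treatment = character(), replicate = integer()
    )
    return(structure(list(events = empty, truth = tibble()),
                     class = "flow_sim"))
  }
  with_seed(config$seed, {
    truth <- draw_cell_truth(config, n, dimer_fraction, efficiency)
    sources <- source_matrix(truth)
    clean <- sources %*% config$mixing$matrix
    autofl <- matrix(
      rlnorm(n * 4, config$autofl_mu, config$autofl_sigma),
      nrow = n
    )
    noise <- matrix(noise_factor(n * 4, config$noise_cv), nrow = n)
    fluor <- (clean + autofl) * noise

    fsc <- 5e4 * rlnorm(n, 0, 0.15)
    fsc_h <- fsc * rlnorm(n, 0, 0.02)
    ssc <- 3e4 * rlnorm(n, 0, 0.25)

    # Doublets: merge with a random partner cell. Area and fluorescence sum;
    # height tracks the larger cell, which is what the FSC-A/FSC-H singlet
    # gate exploits.
    doublet <- runif(n) < config$doublet_fraction
    partner <- sample.int(n, n, replace = TRUE)
    if (any(doublet)) {
      i <- which(doublet)
      p <- partner[i]
      fluor[i, ] <- fluor[i, ] + fluor[p, ]
      fsc[i] <- fsc[i] + fsc[p]
      ssc[i] <- ssc[i] + ssc[p]
      fsc_h[i] <- pmax(fsc_h[i], fsc_h[p])
    }
    fluor <- pmin(fluor, config$saturation_value)

    events <- tibble(
      `FSC-A` = fsc, `FSC-H` = fsc_h, `SSC-A` = ssc,
      `Pacific Blue` = fluor[, "Pacific Blue"],
      FITC = fluor[, "FITC"],
      AmCyan = fluor[, "AmCyan"],
      APC = fluor[, "APC"],
      sample = sample_id, treatment = treatment,
      replicate = as.integer(replicate)
    )
    truth$doublet <- doublet
    truth$cell <- seq_len(n)
    structure(list(events = events, truth = truth), class = "flow_sim")
  })
}

#' Simulate the control samples used by the flow-FRET workflow
#'
#' Produces the five control transfections that calibrate the pipeline, all
#' sharing the configuration's mixing, autofluorescence and noise:
#' \describe{
#'   \item{vector}{empty-vector only (no transfected fluorophores); sets the
#'     transfection-positivity threshold and autofluorescence level}
#'   \item{donor_only, acceptor_only}{truly single-colour samples (no
#'     marker either) for spillover estimation and the double-positive
#'     gate}
#'   \item{negative}{donor and acceptor co-expressed with no dimerization
#'     (cytosolic, non-interacting pair)}
#'   \item{positive}{covalent donor-acceptor fusion: every limiting-chain
#'     copy is in a complex with efficiency `e_fusion`}
#' }
#' Each control uses a sub-seed offset from `config$seed` so the set is
#' reproducible yet mutually independent.
#'
#' @param config A [sim_config()].
#' @return Named list of `flow_sim` objects.
#' @export
simulate_control_set <- function(config) {
  tweak <- function(offset, ...) {
    cfg <- config
    changes <- list(...)
    cfg[names(changes)] <- changes
    cfg$seed <- config$seed + offset
    validate_sim_config(cfg)
  }
  no_dimer <- list(
    dimer_fraction_vehicle = 0, dimer_fraction_max = 0, ligand_dose = 0
  )
  list(
    vector = simulate_flow_sample(
      tweak(101L, p_transfected = 0), sample_id = "vector"
    ),
    donor_only = simulate_flow_sample(
      rlang::exec(tweak, 102L, acceptor_rate = 0, marker_rate = 0,
                  !!!no_dimer),
      sample_id = "donor_only"
    ),
    acceptor_only = simulate_flow_sample(
      rlang::exec(tweak, 103L, donor_rate = 0, marker_rate = 0,
                  !!!no_dimer),
      sample_id = "acceptor_only"
    ),
    negative = simulate_flow_sample(
      rlang::exec(tweak, 104L, !!!no_dimer), sample_id = "negative"
    ),
    positive = simulate_flow_sample(
      tweak(105L, ligand_dose = 0), sample_id = "positive",
      dimer_fraction = 1, efficiency = config$e_fusion
    )
  )
}

#' Simulate a rainbow calibration bead acquisition
#'
#' Each bead subpopulation carries a known reference value (e.g. MEFL); its
#' measured fluorescence is lognormal with mean `true_slope * value` and the
#' requested coefficient of variation. Events from all subpopulations are
#' shuffled together and carry no labels - identifying the subpopulations is
#' the analysis task (see [identify_bead_subpops()]).
#'
#' @param subpop_values Strictly increasing positive reference values.
#' @param true_slope Instrument response, a.u. per reference unit.
#' @param cv Coefficient of variation of the per-bead intensity.
#' @param n_per_subpop Events per subpopulation.
#' @param seed Integer seed.
#' @return Tibble with a single `mfi` column.
#' @export
#' @examples
#' beads <- simulate_bead_set(c(10, 100, 1000), true_slope = 2, cv = 0,
#'                            n_per_subpop = 5, seed = 1)
#' sort(unique(beads$mfi))
simulate_bead_set <- function(subpop_values, true_slope, cv = 0.05,
                              n_per_subpop = 500L, seed = 1L) {
  if (any(subpop_values <= 0) || is.unsorted(subpop_values, strictly = TRUE)) {
    abort("subpop_values must be strictly increasing and positive")
  }
  if (true_slope <= 0) abort("true_slope must be positive")
  with_seed(as.integer(seed), {
    mfi <- unlist(lapply(subpop_values, function(v) {
      m <- true_slope * v
      sdlog <- sqrt(log1p(cv^2))
      rlnorm(n_per_subpop, meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
    }))
    tibble(mfi = mfi[sample.int(length(mfi))])
  })
}
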