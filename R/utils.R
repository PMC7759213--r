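# Channel layout of the FRET cytometer panel: mCerulean donor read in
# Pacific Blue, mVenus acceptor in FITC, sensitized emission (donor
# excitation, acceptor emission) in AmCyan, miRFP670 transfection marker in
# APC, plus the three scatter channels used for cell/singlet gating.

.fluor_channels <- c("Pacific Blue", "FITC", "AmCyan", "APC")
.scatter_channels <- c("FSC-A", "FSC-H", "SSC-A")
.sources <- c("donor", "acceptor", "sensitized", "marker")
.primary_channel <- c(
  donor = "Pacific Blue", acceptor = "FITC",
  sensitized = "AmCyan", marker = "APC"
)

#' Channel roles used throughout the flow-FRET pipeline
#'
#' Returns the mapping from fluorophore role to cytometer channel name:
#' donor (mCerulean) in Pacific Blue, acceptor (mVenus) in FITC, the
#' FRET/sensitized-emission signal in AmCyan and the transfection marker
#' (miRFP670) in APC.
#'
#' @return Named character vector of channel names.
#' @export
#' @examples
#' channel_roles()
channel_roles <- function() .primary_channel

comp_col <- function(channel) paste0("comp_", channel)

is_compensated <- function(events) {
  all(comp_col(c("Pacific Blue", "FITC", "AmCyan")) %in% names(events))
}

# Coerce a simulation result (list with $events) or a plain data frame to an
# event table.
as_event_table <- function(x) {
  if (is.data.frame(x)) {
    return(as_tibble(x))
  }
  if (is.list(x) && is.data.frame(x$events)) {
    return(as_tibble(x$events))
  }
  abort("expected an event table (data frame) or a simulation with $events")
}

# Run code under a temporary RNG seed without touching global state.
with_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}

# Lognormal multiplicative noise factors with unit mean and the requested
# coefficient of variation. cv = 0 gives exactly 1.
noise_factor <- function(n, cv) {
  sdlog <- sqrt(log1p(cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Fold difference between ligand and vehicle arms with propagated error
#'
#' Computes the ligand/vehicle ratio of two summary means together with its
#' first-order (delta-method) standard error,
#' \eqn{SE_F = \sqrt{(SE_L/\mu_V)^2 + (\mu_L SE_V/\mu_V^2)^2}}, which for
#' nonzero means equals \eqn{F\sqrt{(SE_L/\mu_L)^2 + (SE_V/\mu_V)^2}}.
#' The ratio is undefined (flagged, `NA`) when the vehicle mean is not
#' strictly positive.
#'
#' @param mean_ligand,mean_vehicle Arm means (ligand- and vehicle-treated).
#' @param se_ligand,se_vehicle Standard errors of the arm means; `NA` is
#'   treated as zero (single-replicate arms carry no spread estimate).
#' @return One-row tibble with columns `fold`, `fold_se`, `fold_defined`.
#' @export
#' @examples
#' fold_difference(0.4, 0.2, 0.04, 0.02)
fold_difference <- function(mean_ligand, mean_vehicle,
                            se_ligand = 0, se_vehicle = 0) {
  se_ligand <- ifelse(is.na(se_ligand), 0, se_ligand)
  se_vehicle <- ifelse(is.na(se_vehicle), 0, se_vehicle)
  defined <- is.finite(mean_vehicle) & mean_vehicle > 0 & is.finite(mean_ligand)
  fold <- ifelse(defined, mean_ligand / mean_vehicle, NA_real_)
  fold_se <- ifelse(
    defined,
    sqrt((se_ligand / mean_vehicle)^2 +
      (mean_ligand * se_vehicle / mean_vehicle^2)^2),
    NA_real_
  )
  tibble(fold = fold, fold_se = fold_se, fold_defined = defined)
}

# mean/SEM of a numeric vector; SEM is 0 for a single value so that
# downstream propagation treats one replicate as carrying no spread estimate.
mean_sem <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n == 0) {
    return(list(mean = NA_real_, sem = NA_real_, n = 0L))
  }
  s <- if (n > 1) sd(x) / sqrt(n) else 0
  list(mean = mean(x), sem = s, n = n)
}
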