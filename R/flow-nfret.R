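#' Per-cell normalized FRET (NFRET)
#'
#' For each event, NFRET divides the compensated FRET-channel (AmCyan)
#' intensity by the square root of the product of the compensated donor
#' (Pacific Blue) and acceptor (FITC) intensities:
#' \deqn{NFRET_i = \frac{comp\,AmCyan_i}{\sqrt{comp\,PacificBlue_i \times
#'   comp\,FITC_i}}}
#' This expression-normalizes the FRET signal so cells across orders of
#' magnitude of fluorophore expression are comparable. Events whose
#' donor-acceptor product is not strictly positive have no defined NFRET;
#' they are flagged and excluded from all summaries.
#'
#' @param events A compensated event table (see [compensate()]).
#' @return The tibble with `nfret` and `nfret_defined` columns appended.
#' @export
nfret_per_cell <- function(events) {
  events <- as_event_table(events)
  if (!is_compensated(events)) {
    abort("events are not compensated; run compensate() first")
  }
  don <- events[[comp_col("Pacific Blue")]]
  acc <- events[[comp_col("FITC")]]
  fret <- events[[comp_col("AmCyan")]]
  prod <- don * acc
  defined <- is.finite(prod) & prod > 0 & is.finite(fret)
  nfret <- rep(NA_real_, length(prod))
  nfret[defined] <- fret[defined] / sqrt(prod[defined])
  events$nfret <- nfret
  events$nfret_defined <- defined
  events
}

#' Calibrate NFRET between negative and positive controls
#'
#' Rescales NFRET linearly so the mean of a no-interaction (negative)
#' control reads 0 and the mean of a donor-acceptor fusion (positive)
#' control reads 1:
#' \deqn{NFRET_{cal} = (NFRET - NFRET_{neg}) / (NFRET_{pos} - NFRET_{neg})}
#'
#' @param values NFRET values to calibrate.
#' @param negative_mean,positive_mean Mean NFRET of the negative and
#'   positive control populations.
#' @return Calibrated values.
#' @export
#' @examples
#' calibrate_nfret(c(0.1, 0.3, 0.5), 0.1, 0.5)
calibrate_nfret <- function(values, negative_mean, positive_mean) {
  if (!is.finite(negative_mean) || !is.finite(positive_mean) ||
      positive_mean == negative_mean) {
    abort("control means must be finite and distinct")
  }
  (values - negative_mean) / (positive_mean - negative_mean)
}

#' Summarize per-cell NFRET into arm means and the ligand/vehicle fold
#'
#' Replicate means are computed first (over the defined NFRET values of each
#' replicate's gated cells), then averaged within each treatment arm; the
#' arm SEM is the spread across biological replicates. The fold difference
#' divides the ligand-arm mean by the vehicle-arm mean, with standard error
#' propagated to first order (see [fold_difference()]).
#'
#' @param data Tibble of per-cell values with treatment and replicate
#'   columns (e.g. the output of [nfret_per_cell()], possibly row-bound over
#'   replicates).
#' @param values Column of per-cell values (default `nfret`).
#' @param treatment,replicate Grouping columns.
#' @param ligand,vehicle Treatment labels of the two arms.
#' @param pool_cells Average per-replicate means (default, `FALSE`) or pool
#'   all cells within an arm before averaging (`TRUE`).
#' @return One-row tibble: per-arm mean, SEM, replicate and cell counts, and
#'   the fold difference with propagated SE.
#' @export
summarize_sample <- function(data, values = nfret, treatment = treatment,
                             replicate = replicate,
                             ligand = "ligand", vehicle = "vehicle",
                             pool_cells = FALSE) {
  data <- as_event_table(data)
  grouped <- data |>
    filter(is.finite({{ values }})) |>
    group_by(.treat = {{ treatment }}, .rep = {{ replicate }})
  if (pool_cells) {
    grouped <- data |>
      filter(is.finite({{ values }})) |>
      group_by(.treat = {{ treatment }})
  }
  rep_means <- grouped |>
    summarise(.mean = mean({{ values }}), .n = n(), .groups = "drop")

  arm <- function(label) {
    rows <- rep_means[rep_means$.treat == label, ]
    if (nrow(rows) == 0) {
      return(list(mean = NA_real_, sem = NA_real_, n_rep = 0L, n_cells = 0L))
    }
    ms <- mean_sem(rows$.mean)
    list(mean = ms$mean, sem = ms$sem, n_rep = nrow(rows),
         n_cells = sum(rows$.n))
  }
  lig <- arm(ligand)
  veh <- arm(vehicle)
  fd <- fold_difference(lig$mean, veh$mean, lig$sem, veh$sem)
  tibble(
    mean_ligand = lig$mean, sem_ligand = lig$sem,
    n_rep_ligand = lig$n_rep, n_cells_ligand = lig$n_cells,
    mean_vehicle = veh$mean, sem_vehicle = veh$sem,
    n_rep_vehicle = veh$n_rep, n_cells_vehicle = veh$n_cells,
    fold = fd$fold, fold_se = fd$fold_se, fold_defined = fd$fold_defined
  )
}
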