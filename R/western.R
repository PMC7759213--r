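#' Western-blot expression normalization across exposures
#'
#' For each exposure of a blot, the receptor band of every lane is expressed
#' as a percent of the total receptor signal over the usable lanes of that
#' exposure, and likewise for the co-transfected NanoLuciferase loading
#' control - percent-of-total cancels any overall gain difference between
#' exposures. Lanes flagged non-detectable or saturated in an exposure are
#' excluded from that exposure only (both from their own percent and from
#' the total). Percents are then averaged across the lane's usable
#' exposures, the receptor percent divided by the loading-control percent,
#' and the quotient referenced to a designated internal-control lane. The
#' reciprocal of the relative expression is also reported as the suggested
#' plasmid-dose scaling for expression matching.
#'
#' @param band_table Tibble with columns `exposure`, `lane`, `mesa`
#'   (receptor band intensity), `nanoluc` (loading-control intensity) and
#'   optional logical `mesa_ok`/`nanoluc_ok` usability flags (default all
#'   usable).
#' @param control_lane Lane label of the internal cross-comparison control.
#' @return Tibble, one row per lane: averaged percents, `ratio`,
#'   `relative_expression` (control lane = 1) and `dose_factor`.
#' @export
western_normalize <- function(band_table, control_lane) {
  bands <- as_event_table(band_table)
  if (!"mesa_ok" %in% names(bands)) bands$mesa_ok <- TRUE
  if (!"nanoluc_ok" %in% names(bands)) bands$nanoluc_ok <- TRUE
  if (!control_lane %in% bands$lane) {
    abort(paste0("control lane '", control_lane, "' not in the band table"))
  }

  pct <- bands |>
    group_by(exposure) |>
    mutate(
      mesa_pct = ifelse(
        mesa_ok, 100 * mesa / sum(mesa[mesa_ok]), NA_real_
      ),
      nanoluc_pct = ifelse(
        nanoluc_ok, 100 * nanoluc / sum(nanoluc[nanoluc_ok]), NA_real_
      )
    ) |>
    ungroup()

  lanes <- pct |>
    group_by(lane) |>
    summarise(
      mesa_pct = mean(mesa_pct, na.rm = TRUE),
      nanoluc_pct = mean(nanoluc_pct, na.rm = TRUE),
      n_exposures_mesa = sum(mesa_ok),
      n_exposures_nanoluc = sum(nanoluc_ok),
      .groups = "drop"
    ) |>
    mutate(ratio = mesa_pct / nanoluc_pct)

  ctrl <- lanes$ratio[lanes$lane == control_lane]
  if (!is.finite(ctrl)) {
    abort("internal-control lane has no usable exposures")
  }
  lanes |>
    mutate(
      relative_expression = ratio / ctrl,
      dose_factor = 1 / relative_expression
    )
}
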