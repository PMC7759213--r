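#' Reporter-output summary in calibrated units with fold difference
#'
#' Implements the reporter quantification chain: the mean fluorescence
#' intensity of each arm is averaged across biological replicates, the mean
#' of the autofluorescence control is subtracted, and the result is
#' converted to calibrated units (MEFL/MEPTR) through the bead slope. The
#' fold difference divides the ligand arm by the vehicle arm. Standard
#' error is propagated to first order through every step (replicate SEM,
#' autofluorescence SEM, calibration slope SE, ratio).
#'
#' @param data Tibble with `treatment` and `mfi` columns, one row per
#'   biological replicate.
#' @param autofluorescence Numeric vector of autofluorescence-control MFIs
#'   (one per replicate of the control group).
#' @param calibration A [fit_bead_slope()] result.
#' @param ligand,vehicle Treatment labels.
#' @return A `reporter_summary` list: `arms` (tibble, one row per
#'   treatment: mfi, background-subtracted mfi, mefl, SEs, n) and `fold`
#'   (one-row tibble from [fold_difference()]).
#' @export
reporter_summary <- function(data, autofluorescence, calibration,
                             ligand = "ligand", vehicle = "vehicle") {
  data <- as_event_table(data)
  if (length(autofluorescence) == 0) {
    abort("an autofluorescence control is required")
  }
  af <- mean_sem(autofluorescence)
  slope <- calibration$slope
  slope_se <- calibration$slope_se
  if (!is.finite(slope_se)) slope_se <- 0

  arms <- data |>
    group_by(treatment) |>
    summarise(
      n = n(),
      mfi_se = if (n() > 1) sd(mfi) / sqrt(n()) else 0,
      mfi = mean(mfi),
      .groups = "drop"
    ) |>
    mutate(
      mfi_bg = mfi - af$mean,
      mfi_bg_se = sqrt(mfi_se^2 + af$sem^2),
      mefl = mfi_bg / slope,
      mefl_se = sqrt((mfi_bg_se / slope)^2 +
                       (mfi_bg * slope_se / slope^2)^2)
    ) |>
    select(treatment, n, mfi, mfi_se, mfi_bg, mfi_bg_se, mefl, mefl_se)

  pick <- function(label, col) {
    v <- arms[[col]][arms$treatment == label]
    if (length(v) == 0) NA_real_ else v
  }
  fold <- fold_difference(
    pick(ligand, "mefl"), pick(vehicle, "mefl"),
    pick(ligand, "mefl_se"), pick(vehicle, "mefl_se")
  )
  structure(list(arms = arms, fold = fold), class = "reporter_summary")
}

#' @export
print.reporter_summary <- function(x, ...) {
  cat("<reporter_summary>\n")
  print(x$arms)
  cat("fold difference:", signif(x$fold$fold, 4),
      "+/-", signif(x$fold$fold_se, 4), "\n")
  invisible(x)
}
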