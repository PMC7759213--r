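#' Dual-luciferase plate normalization
#'
#' Per well: the technical replicates of each luminescence readout are
#' averaged; the autoluminescence background (mean over the vector-only
#' wells) is subtracted per readout; the Firefly signal is divided by the
#' Renilla signal; and all quotients are linearly scaled so that the mean
#' quotient of the reporter-only condition equals exactly 1 a.u. Standard
#' error is propagated through each step (technical-replicate SEM,
#' background SEM, ratio, scaling). Wells whose background-subtracted
#' Renilla signal is not strictly positive are flagged invalid.
#'
#' @param plate Tibble with columns `condition`, `well`, `firefly`,
#'   `renilla`; one row per technical replicate.
#' @param vector_condition Label of the vector-only (autoluminescence)
#'   wells.
#' @param reporter_condition Label of the reporter-only anchor condition.
#' @return Tibble, one row per well: background-subtracted means,
#'   Firefly/Renilla `ratio`, `normalized` activity with `normalized_se`,
#'   and a `valid` flag.
#' @export
luciferase_normalize <- function(plate, vector_condition = "vector",
                                 reporter_condition = "reporter") {
  plate <- as_event_table(plate)
  for (needed in c(vector_condition, reporter_condition)) {
    if (!needed %in% plate$condition) {
      abort(paste0("condition '", needed, "' not present in the plate"))
    }
  }

  wells <- plate |>
    group_by(condition, well) |>
    summarise(
      n_tech = n(),
      firefly_se = if (n() > 1) sd(firefly) / sqrt(n()) else 0,
      renilla_se = if (n() > 1) sd(renilla) / sqrt(n()) else 0,
      firefly = mean(firefly),
      renilla = mean(renilla),
      .groups = "drop"
    )

  bg <- wells |> filter(condition == vector_condition)
  bg_f <- mean_sem(bg$firefly)
  bg_r <- mean_sem(bg$renilla)

  wells <- wells |>
    mutate(
      firefly_bg = firefly - bg_f$mean,
      firefly_bg_se = sqrt(firefly_se^2 + bg_f$sem^2),
      renilla_bg = renilla - bg_r$mean,
      renilla_bg_se = sqrt(renilla_se^2 + bg_r$sem^2),
      valid = is.finite(renilla_bg) & renilla_bg > 0,
      ratio = ifelse(valid, firefly_bg / renilla_bg, NA_real_),
      ratio_se = ifelse(
        valid,
        sqrt((firefly_bg_se / renilla_bg)^2 +
               (firefly_bg * renilla_bg_se / renilla_bg^2)^2),
        NA_real_
      )
    )

  anchor <- wells |> filter(condition == reporter_condition, valid)
  if (nrow(anchor) == 0) {
    abort("no valid reporter-only wells to anchor the scaling")
  }
  sc <- mean_sem(anchor$ratio)
  wells |>
    mutate(
      normalized = ratio / sc$mean,
      normalized_se = sqrt((ratio_se / sc$mean)^2 +
                             (ratio * sc$sem / sc$mean^2)^2)
    )
}
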