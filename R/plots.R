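#' @describeIn pixel_nfret Heatmap of the per-pixel NFRET matrix; masked
#'   pixels are blank.
#' @param object A `pixel_nfret` result.
#' @param which `"nfret"` or `"fc"`.
#' @param ... Unused.
#' @export
autoplot.pixel_nfret <- function(object, which = c("nfret", "fc"), ...) {
  which <- arg_match(which)
  m <- object[[which]]
  df <- tibble(
    row = as.vector(row(m)),
    col = as.vector(col(m)),
    value = as.vector(m)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = col, y = row, fill = value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(na.value = "grey50") +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      title = paste0(object$sample_id, " / ", object$field_id),
      fill = if (which == "nfret") "NFRET" else "Fc"
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn distance_regression Scatter of the points with the fitted
#'   line.
#' @param object A `distance_regression`.
#' @export
autoplot.distance_regression <- function(object, ...) {
  pts <- attr(object, "points")
  ggplot2::ggplot(pts, ggplot2::aes(x = distance, y = fold)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_abline(slope = object$slope,
                         intercept = object$intercept) +
    ggplot2::labs(
      x = "ECD C-terminal distance (Å)",
      y = "NFRET fold difference",
      subtitle = sprintf("y = %.3fx + %.2f, R² = %.2f",
                         object$slope, object$intercept, object$r_squared)
    ) +
    ggplot2::theme_classic()
}

#' @describeIn fit_bead_slope Calibration points with the origin-constrained
#'   fit line.
#' @param object A `bead_calibration`.
#' @export
autoplot.bead_calibration <- function(object, ...) {
  pts <- attr(object, "points")
  ggplot2::ggplot(pts, ggplot2::aes(x = reference, y = mfi)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_abline(slope = object$slope, intercept = 0) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Reference value (MEFL)", y = "MFI (a.u.)") +
    ggplot2::theme_classic()
}

#' NFRET distributions of gated cells
#'
#' Density plot of per-cell NFRET, split by a grouping column when one is
#' given - the standard way to compare a sample against its negative and
#' positive controls.
#'
#' @param data Tibble with an `nfret` column (see [nfret_per_cell()]).
#' @param group Optional grouping column (e.g. `sample` or `treatment`).
#' @return A ggplot object.
#' @export
plot_nfret <- function(data, group = NULL) {
  data <- as_event_table(data)
  data <- filter(data, is.finite(nfret))
  p <- ggplot2::ggplot(data, ggplot2::aes(x = nfret))
  if (!quo_is_null(enquo(group))) {
    p <- ggplot2::ggplot(
      data, ggplot2::aes(x = nfret, colour = factor({{ group }}))
    ) +
      ggplot2::labs(colour = as_label(enquo(group)))
  }
  p + ggplot2::geom_density() +
    ggplot2::labs(x = "NFRET", y = "density") +
    ggplot2::theme_classic()
}
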