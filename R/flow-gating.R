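# bilinear interpolation of a kde2d surface at arbitrary points
interp_density <- function(kd, x, y) {
  ix <- findInterval(x, kd$x, all.inside = TRUE)
  iy <- findInterval(y, kd$y, all.inside = TRUE)
  x0 <- kd$x[ix]; x1 <- kd$x[ix + 1]
  y0 <- kd$y[iy]; y1 <- kd$y[iy + 1]
  wx <- (x - x0) / (x1 - x0)
  wy <- (y - y0) / (y1 - y0)
  wx <- pmin(pmax(wx, 0), 1)
  wy <- pmin(pmax(wy, 0), 1)
  z <- kd$z
  z[cbind(ix, iy)] * (1 - wx) * (1 - wy) +
    z[cbind(ix + 1, iy)] * wx * (1 - wy) +
    z[cbind(ix, iy + 1)] * (1 - wx) * wy +
    z[cbind(ix + 1, iy + 1)] * wx * wy
}

#' Density gate on the scatter channels
#'
#' Keeps the events lying in the densest region of the (FSC-A, SSC-A) plane,
#' the automated analogue of the manually drawn cell gate: a 2-D kernel
#' density is estimated and the events above the density quantile that
#' retains `keep_fraction` of them are kept.
#'
#' @param events Event table with `FSC-A` and `SSC-A` columns.
#' @param keep_fraction Fraction of events the gate retains.
#' @param n_grid Kernel-density grid resolution.
#' @return The gated event tibble.
#' @export
gate_cells <- function(events, keep_fraction = 0.75, n_grid = 64) {
  events <- as_event_table(events)
  if (nrow(events) == 0) {
    warn("empty event table; returning it unchanged")
    return(events)
  }
  kd <- MASS::kde2d(events[["FSC-A"]], events[["SSC-A"]], n = n_grid)
  dens <- interp_density(kd, events[["FSC-A"]], events[["SSC-A"]])
  events[dens >= quantile(dens, 1 - keep_fraction, names = FALSE), ]
}

#' Singlet gate on the forward-scatter area/height relationship
#'
#' Doublets (two coincident cells) roughly double the forward-scatter area
#' but not its height. Events are kept when their FSC-A/FSC-H ratio lies
#' within a relative band around the population median ratio.
#'
#' @param events Event table with `FSC-A` and `FSC-H` columns.
#' @param tolerance Half-width of the band, relative to the median ratio.
#' @return The gated event tibble.
#' @export
gate_singlets <- function(events, tolerance = 0.15) {
  events <- as_event_table(events)
  if (nrow(events) == 0) {
    warn("empty event table; returning it unchanged")
    return(events)
  }
  ratio <- events[["FSC-A"]] / events[["FSC-H"]]
  med <- median(ratio)
  events[abs(ratio - med) <= tolerance * med, ]
}

#' @describeIn gate_cells Cell gate followed by the singlet gate, the fixed
#'   gating order of the workflow.
#' @param tolerance Relative half-width of the singlet FSC-A/FSC-H band.
#' @export
gate_cells_singlets <- function(events, keep_fraction = 0.75,
                                tolerance = 0.15, n_grid = 64) {
  gated <- gate_cells(events, keep_fraction, n_grid)
  if (nrow(gated) == 0) {
    return(gated)
  }
  gate_singlets(gated, tolerance)
}

#' Positivity threshold from a negative control
#'
#' Returns the `(1 - max_false_rate)` linear-interpolation quantile of a
#' channel in a negative (non-fluorescent or single-colour) control, so that
#' gating events strictly above the threshold re-includes at most
#' `max_false_rate` of the control population.
#'
#' @param negative_control Event table of the control population.
#' @param channel Channel (column) name.
#' @param max_false_rate Allowed false-inclusion rate, in (0, 1).
#' @return Threshold intensity (scalar).
#' @export
#' @examples
#' ctrl <- tibble::tibble(APC = 1:100)
#' positivity_threshold(ctrl, "APC", 0.01) # 99.01
positivity_threshold <- function(negative_control, channel,
                                 max_false_rate = 0.01) {
  if (max_false_rate <= 0 || max_false_rate >= 1) {
    abort("max_false_rate must lie strictly between 0 and 1")
  }
  events <- as_event_table(negative_control)
  x <- events[[channel]]
  if (is.null(x) || length(x) == 0) {
    abort(paste0("negative control has no events in channel '", channel, "'"))
  }
  quantile(x, 1 - max_false_rate, names = FALSE, type = 7)
}
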