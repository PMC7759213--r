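#' Estimate a spillover matrix from single-colour controls
#'
#' For each single-fluorophore control, the coefficient of that fluorophore
#' into every off-channel is the origin-constrained least-squares slope
#' (\eqn{\sum xy / \sum x^2}) of the autofluorescence-subtracted off-channel
#' intensity against the autofluorescence-subtracted primary-channel
#' intensity, computed over the control's positive events. The matrix
#' diagonal is fixed at 1; sources without a control (always the sensitized
#' emission, usually the marker) keep identity rows.
#'
#' @param controls Named list of single-colour event tables (or `flow_sim`
#'   objects); names must be among `"donor"`, `"acceptor"`, `"marker"`.
#' @param autofluorescence Either a vector-only (untransfected) event table,
#'   from which per-channel autofluorescence means and positivity thresholds
#'   are derived, or a named numeric vector of per-channel means. `NULL`
#'   means no autofluorescence subtraction and positivity at zero.
#' @param max_false_rate False-inclusion rate for the positivity threshold
#'   when a vector-only table is supplied.
#' @param min_events Minimum positive events required per control.
#' @return A `spillover_model`.
#' @export
estimate_spillover <- function(controls, autofluorescence = NULL,
                               max_false_rate = 0.01, min_events = 100L) {
  if (is.null(names(controls)) ||
      !all(names(controls) %in% c("donor", "acceptor", "marker"))) {
    abort("controls must be named among 'donor', 'acceptor', 'marker'")
  }

  af_table <- NULL
  af_mean <- setNames(rep(0, 4), .fluor_channels)
  if (is.data.frame(autofluorescence) ||
      (is.list(autofluorescence) && !is.null(autofluorescence$events))) {
    af_table <- as_event_table(autofluorescence)
    for (ch in .fluor_channels) af_mean[ch] <- mean(af_table[[ch]])
  } else if (is.numeric(autofluorescence)) {
    af_mean[names(autofluorescence)] <- autofluorescence
  }

  m <- diag(4)
  dimnames(m) <- list(.sources, .fluor_channels)
  n_pos <- integer(0)

  for (src in names(controls)) {
    ev <- as_event_table(controls[[src]])
    primary <- .primary_channel[[src]]
    thr <- if (!is.null(af_table)) {
      positivity_threshold(af_table, primary, max_false_rate)
    } else {
      0
    }
    pos <- ev[[primary]] > thr
    if (sum(pos) < min_events) {
      abort(paste0(
        "single-colour control for '", src, "' has only ", sum(pos),
        " positive events (need >= ", min_events, ")"
      ))
    }
    x <- ev[[primary]][pos] - af_mean[[primary]]
    for (ch in setdiff(.fluor_channels, primary)) {
      y <- ev[[ch]][pos] - af_mean[[ch]]
      m[src, ch] <- sum(x * y) / sum(x^2)
    }
    n_pos[src] <- sum(pos)
  }

  coefs <- c(
    a = m["acceptor", "AmCyan"], b = m["acceptor", "Pacific Blue"],
    c = m["donor", "FITC"], d = m["donor", "AmCyan"]
  )
  new_spillover_model(
    m, coefficients = coefs, source = "estimated",
    details = list(n_positive = n_pos, autofluorescence = af_mean,
                   max_false_rate = max_false_rate)
  )
}

#' Compensate an event table for spectral spillover
#'
#' Multiplies each event's channel vector by the inverse of the spillover
#' matrix, recovering the underlying per-fluorophore signals. Negative
#' compensated values are preserved (they carry the noise structure needed
#' for unbiased population statistics). Compensated intensities are added as
#' `comp_`-prefixed columns alongside the raw channels.
#'
#' @param events Event table (or `flow_sim`) with the fluorescence channels.
#' @param model A `spillover_model` from [estimate_spillover()] or
#'   [spillover_matrix()].
#' @return The event tibble with `comp_<channel>` columns appended.
#' @export
compensate <- function(events, model) {
  events <- as_event_table(events)
  chans <- intersect(.fluor_channels, names(events))
  if (length(chans) < 2) {
    abort("events must contain at least two fluorescence channels")
  }
  srcs <- names(.primary_channel)[.primary_channel %in% chans]
  sub <- model$matrix[srcs, chans, drop = FALSE]
  inv <- tryCatch(
    solve(sub),
    error = function(e) abort("spillover matrix is singular", parent = e)
  )
  raw <- as.matrix(events[, chans])
  comp <- raw %*% inv
  colnames(comp) <- comp_col(chans)
  dplyr::bind_cols(events, as_tibble(comp))
}
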