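#' End-to-end flow-FRET analysis of one sample
#'
#' Runs the complete workflow on a sample given its control set: (1) cell
#' and singlet gating; (2) spillover estimation from the gated single-colour
#' controls (unless a model is supplied); (3) compensation; (4) the
#' transfected and double-positive gates, with thresholds drawn so that at
#' most `max_false_rate` of the corresponding negative population is
#' included (vector-only control for the marker, each single-colour control
#' for the opposite fluorophore); (5) per-cell NFRET; and optionally (6)
#' calibration of NFRET between the negative (co-expressed, non-interacting)
#' and positive (fusion) controls.
#'
#' @param sample Event table or `flow_sim` of the sample to analyze.
#' @param controls Named list with elements `vector`, `donor_only`,
#'   `acceptor_only` and, when `calibrate = TRUE`, `negative` and
#'   `positive`; see [simulate_control_set()].
#' @param model Optional `spillover_model`; estimated from the controls when
#'   `NULL`.
#' @param keep_fraction,singlet_tolerance Gating parameters
#'   (see [gate_cells()] and [gate_singlets()]).
#' @param max_false_rate False-inclusion rate of the positivity gates.
#' @param calibrate Calibrate NFRET between the negative/positive controls?
#' @return A `flow_fret_analysis` list: `cells` (gated, compensated tibble
#'   with `nfret`), `model`, `thresholds`, `mean_nfret`, `n_cells`, and when
#'   calibrated the control means and `mean_nfret_calibrated`.
#' @export
analyze_flow_fret <- function(sample, controls, model = NULL,
                              keep_fraction = 0.75, singlet_tolerance = 0.15,
                              max_false_rate = 0.01, calibrate = FALSE) {
  needed <- c("vector", "donor_only", "acceptor_only")
  if (calibrate) needed <- c(needed, "negative", "positive")
  missing <- setdiff(needed, names(controls))
  if (length(missing) > 0) {
    abort(paste("missing controls:", paste(missing, collapse = ", ")))
  }

  g <- function(x) {
    gate_cells_singlets(as_event_table(x), keep_fraction, singlet_tolerance)
  }
  cells <- g(sample)
  vec <- g(controls$vector)
  don <- g(controls$donor_only)
  acc <- g(controls$acceptor_only)

  model <- model %||% estimate_spillover(
    list(donor = don, acceptor = acc),
    autofluorescence = vec, max_false_rate = max_false_rate
  )

  cells <- compensate(cells, model)
  vec_c <- compensate(vec, model)
  don_c <- compensate(don, model)
  acc_c <- compensate(acc, model)

  thresholds <- c(
    marker = positivity_threshold(vec_c, comp_col("APC"), max_false_rate),
    donor = positivity_threshold(acc_c, comp_col("Pacific Blue"),
                                 max_false_rate),
    acceptor = positivity_threshold(don_c, comp_col("FITC"), max_false_rate)
  )

  double_pos <- function(ev) {
    ev[ev[[comp_col("APC")]] > thresholds[["marker"]] &
         ev[[comp_col("Pacific Blue")]] > thresholds[["donor"]] &
         ev[[comp_col("FITC")]] > thresholds[["acceptor"]], ]
  }
  cells <- nfret_per_cell(double_pos(cells))

  out <- list(
    cells = cells,
    model = model,
    thresholds = thresholds,
    mean_nfret = mean(cells$nfret[cells$nfret_defined]),
    n_cells = sum(cells$nfret_defined),
    calibrated = calibrate
  )

  if (calibrate) {
    ctrl_mean <- function(x) {
      cc <- nfret_per_cell(double_pos(compensate(g(x), model)))
      mean(cc$nfret[cc$nfret_defined])
    }
    out$negative_mean <- ctrl_mean(controls$negative)
    out$positive_mean <- ctrl_mean(controls$positive)
    out$cells$nfret_calibrated <- calibrate_nfret(
      out$cells$nfret, out$negative_mean, out$positive_mean
    )
    out$mean_nfret_calibrated <- calibrate_nfret(
      out$mean_nfret, out$negative_mean, out$positive_mean
    )
  }
  structure(out, class = "flow_fret_analysis")
}

#' @export
print.flow_fret_analysis <- function(x, ...) {
  cat("<flow_fret_analysis> ", x$n_cells, " cells | mean NFRET ",
      signif(x$mean_nfret, 4), sep = "")
  if (isTRUE(x$calibrated)) {
    cat(" | calibrated ", signif(x$mean_nfret_calibrated, 4), sep = "")
  }
  cat("\n")
  invisible(x)
}

#' @describeIn analyze_flow_fret One-row summary of a fitted analysis.
#' @param x A `flow_fret_analysis`.
#' @param ... Unused.
#' @export
glance.flow_fret_analysis <- function(x, ...) {
  out <- tibble(
    mean_nfret = x$mean_nfret,
    n_cells = x$n_cells,
    threshold_marker = x$thresholds[["marker"]],
    threshold_donor = x$thresholds[["donor"]],
    threshold_acceptor = x$thresholds[["acceptor"]]
  )
  if (isTRUE(x$calibrated)) {
    out$mean_nfret_calibrated <- x$mean_nfret_calibrated
    out$negative_mean <- x$negative_mean
    out$positive_mean <- x$positive_mean
  }
  out
}
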