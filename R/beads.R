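#' Identify calibration-bead subpopulations
#'
#' Partitions the bead intensities into `k` clusters by 1-D k-means on the
#' log intensity, initialized at sorted quantiles of the log distribution
#' (which makes the fit deterministic), and returns the per-cluster mean
#' intensity in ascending order.
#'
#' @param bead_events Tibble of bead events (see [simulate_bead_set()]).
#' @param k Number of subpopulations (6 for RCP, 9 for URCP reagents).
#' @param channel Intensity column name.
#' @return Numeric vector of `k` subpopulation mean intensities, ascending.
#' @export
identify_bead_subpops <- function(bead_events, k, channel = "mfi") {
  bead_events <- as_event_table(bead_events)
  x <- bead_events[[channel]]
  if (is.null(x)) abort(paste0("no channel '", channel, "' in bead events"))
  if (length(x) < 10 * k) {
    abort("need at least 10 events per requested subpopulation")
  }
  if (any(x <= 0)) abort("bead intensities must be positive")
  if (k == 1) {
    return(mean(x))
  }
  lx <- log(x)
  init <- quantile(lx, probs = (seq_len(k) - 0.5) / k, names = FALSE, type = 7)
  if (length(unique(init)) < k) {
    abort(paste0("fewer than ", k, " distinct subpopulations found"))
  }
  fit <- tryCatch(
    kmeans(lx, centers = matrix(init, ncol = 1), iter.max = 100),
    error = function(e) {
      abort(paste0("fewer than ", k, " distinct subpopulations found"),
            parent = e)
    }
  )
  if (length(unique(fit$cluster)) < k) {
    abort(paste0("fewer than ", k, " distinct subpopulations found"))
  }
  sort(as.numeric(tapply(x, fit$cluster, mean)))
}

#' Origin-constrained bead calibration curve
#'
#' Fits measured subpopulation intensities against the manufacturer-supplied
#' reference values (MEFL/MEPTR) by least squares through the origin (0 MFI
#' corresponds to 0 reference units): `slope = sum(x*y) / sum(x^2)` with `x`
#' the reference values and `y` the intensities. The slope (a.u. per
#' reference unit) is the conversion factor; its standard error comes from
#' the regression residuals.
#'
#' @param subpop_mfis Measured subpopulation mean intensities.
#' @param reference_values Manufacturer reference values, same length.
#' @return A `bead_calibration` object (one-row tibble with `slope`,
#'   `slope_se`, `n_subpops`; the points are kept as an attribute).
#' @export
#' @examples
#' cal <- fit_bead_slope(c(20, 200, 2000), c(10, 100, 1000))
#' cal$slope # 2
fit_bead_slope <- function(subpop_mfis, reference_values) {
  if (length(subpop_mfis) != length(reference_values)) {
    abort("subpop_mfis and reference_values must have the same length")
  }
  if (length(subpop_mfis) < 1) abort("at least one subpopulation is required")
  x <- as.numeric(reference_values)
  y <- as.numeric(subpop_mfis)
  if (all(x == 0)) abort("reference values cannot all be zero")
  slope <- sum(x * y) / sum(x^2)
  n <- length(x)
  slope_se <- if (n >= 2) {
    sqrt(sum((y - slope * x)^2) / (n - 1) / sum(x^2))
  } else {
    NA_real_
  }
  out <- tibble(slope = slope, slope_se = slope_se, n_subpops = n)
  attr(out, "points") <- tibble(reference = x, mfi = y)
  class(out) <- c("bead_calibration", class(out))
  out
}

#' Convert background-subtracted intensities to calibrated units
#'
#' Applies a bead calibration: `(mfi - background) / slope`. Background is
#' subtracted before conversion, matching the order of the reporter
#' workflow.
#'
#' @param mfi Measured intensities.
#' @param calibration A [fit_bead_slope()] result.
#' @param background Autofluorescence to subtract (default 0).
#' @return Calibrated values (MEFL/MEPTR).
#' @export
mfi_to_mefl <- function(mfi, calibration, background = 0) {
  (mfi - background) / calibration$slope
}

#' @describeIn fit_bead_slope Calibration points with fitted values.
#' @param x A `bead_calibration`.
#' @param ... Unused.
#' @export
tidy.bead_calibration <- function(x, ...) {
  pts <- attr(x, "points")
  pts$fitted <- x$slope * pts$reference
  pts
}
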