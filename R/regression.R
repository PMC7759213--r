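#' Regression of NFRET fold difference on ectodomain C-terminal distance
#'
#' Ordinary least squares of the ligand-induced NFRET fold difference
#' against the crystal-structure distance between the C-termini of the
#' ligand-bound ectodomains. A negative slope indicates that receptor pairs
#' whose ligand-binding domains hold the chains further apart show weaker
#' ligand-induced association.
#'
#' @param data Tibble of one point per receptor system.
#' @param distance,fold Columns holding the distance (Angstrom) and the
#'   NFRET fold difference.
#' @return A `distance_regression` one-row tibble: `slope` (per Angstrom),
#'   `intercept`, `r_squared`, `p_value` (two-tailed t-test on the slope)
#'   and `n`. The underlying `lm` fit is kept as an attribute.
#' @export
#' @examples
#' pts <- tibble::tibble(distance = c(8, 22, 35, 50),
#'                       fold = 2.9 - 0.027 * c(8, 22, 35, 50))
#' distance_regression(pts)
distance_regression <- function(data, distance = distance, fold = fold) {
  data <- as_event_table(data)
  x <- pull(data, {{ distance }})
  y <- pull(data, {{ fold }})
  if (length(x) < 3) abort("at least three points are required")
  if (var(x) == 0) abort("distances are all identical; slope is undefined")
  fit <- lm(y ~ x)
  s <- suppressWarnings(summary(fit))
  cf <- s$coefficients
  out <- tibble(
    slope = cf["x", "Estimate"],
    intercept = cf["(Intercept)", "Estimate"],
    # a flat response has zero explainable variance; report R^2 = 0 rather
    # than 0/0
    r_squared = if (var(y) == 0) 0 else s$r.squared,
    p_value = cf["x", "Pr(>|t|)"],
    n = length(x)
  )
  attr(out, "fit") <- fit
  attr(out, "points") <- tibble(distance = x, fold = y)
  class(out) <- c("distance_regression", class(out))
  out
}

#' @describeIn distance_regression Coefficient table (broom convention).
#' @param x A `distance_regression`.
#' @param ... Unused.
#' @export
tidy.distance_regression <- function(x, ...) {
  cf <- suppressWarnings(summary(attr(x, "fit")))$coefficients
  tibble(
    term = c("(Intercept)", "distance"),
    estimate = unname(cf[, "Estimate"]),
    std.error = unname(cf[, "Std. Error"]),
    statistic = unname(cf[, "t value"]),
    p.value = unname(cf[, "Pr(>|t|)"])
  )
}

#' @describeIn distance_regression One-row model summary.
#' @export
glance.distance_regression <- function(x, ...) {
  tibble(
    r.squared = x$r_squared,
    slope = x$slope,
    intercept = x$intercept,
    p.value = x$p_value,
    nobs = x$n
  )
}
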