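#' Autofluorescence thresholds from vector-only fields
#'
#' The per-channel threshold is the stated percentile (default the 99.9th)
#' of pixel intensity over all pixels of all vector-only (untransfected)
#' fields pooled together - pooling the pixel distributions, not averaging
#' per-field statistics. Linear-interpolation quantiles are used.
#'
#' @param vector_only_fields An [image_field()] or list of them.
#' @param percentile Percentile as a fraction in (0, 1).
#' @return Named numeric vector `c(dd, aa, da)`.
#' @export
autofluorescence_thresholds <- function(vector_only_fields,
                                        percentile = 0.999) {
  fields <- as_field_list(vector_only_fields)
  if (length(fields) == 0) abort("at least one vector-only field is required")
  if (percentile <= 0 || percentile >= 1) {
    abort("percentile must lie strictly between 0 and 1")
  }
  pooled <- function(chan) {
    unlist(lapply(fields, function(f) as.vector(f[[chan]])))
  }
  vapply(
    c(dd = "dd", aa = "aa", da = "da"),
    function(chan) quantile(pooled(chan), percentile, names = FALSE, type = 7),
    numeric(1)
  )
}

#' Mask sub-threshold and saturated pixels
#'
#' Pixels at or below the channel's autofluorescence threshold are set to
#' zero; pixels at or above the saturation value in any channel are removed
#' from the field's validity mask and excluded from every downstream average
#' (bleed-through parameters, corrected FRET, NFRET). Zeroing ties at the
#' threshold keeps the fraction of background pixels that survive masking
#' within the threshold's nominal false-inclusion rate even when intensities
#' are integer-quantized (where many pixels can share the exact threshold
#' value); for continuous intensities the two conventions coincide.
#'
#' @param field An [image_field()].
#' @param thresholds Named vector `c(dd, aa, da)` from
#'   [autofluorescence_thresholds()].
#' @param saturation_value Defaults to the field's declared saturation.
#' @return The masked [image_field()].
#' @export
mask_pixels <- function(field, thresholds,
                        saturation_value = field$saturation_value) {
  if (!all(c("dd", "aa", "da") %in% names(thresholds))) {
    abort("thresholds must cover channels dd, aa and da")
  }
  saturated <- field$dd >= saturation_value |
    field$aa >= saturation_value |
    field$da >= saturation_value
  field$valid <- field$valid & !saturated
  for (chan in c("dd", "aa", "da")) {
    x <- field[[chan]]
    x[x <= thresholds[[chan]]] <- 0
    field[[chan]] <- x
  }
  field$masked <- TRUE
  field
}

#' Spectral bleed-through parameters from single-colour fields
#'
#' From acceptor-only fields: `a`, the mean pixel-wise ratio DA/AA, and `b`,
#' the mean DD/AA. From donor-only fields: `c`, the mean AA/DD, and `d`, the
#' mean DA/DD. Ratios are averaged over all valid pixels pooled across the
#' provided (masked) fields, excluding pixels whose denominator is zero
#' (infinite or undefined ratios).
#'
#' @param donor_only,acceptor_only Masked [image_field()]s (or lists).
#' @return A `bleedthrough_params` object with elements `a`, `b`, `c`, `d`.
#' @export
estimate_bleedthrough <- function(donor_only, acceptor_only) {
  donor_only <- as_field_list(donor_only)
  acceptor_only <- as_field_list(acceptor_only)

  ratio_mean <- function(fields, num, den, label) {
    nums <- unlist(lapply(fields, function(f) as.vector(f[[num]][f$valid])))
    dens <- unlist(lapply(fields, function(f) as.vector(f[[den]][f$valid])))
    ok <- is.finite(nums) & is.finite(dens) & dens > 0
    if (!any(ok)) {
      abort(paste0("no valid pixels for parameter '", label,
                   "' (all denominators zero)"))
    }
    c(mean(nums[ok] / dens[ok]), sum(ok))
  }

  a <- ratio_mean(acceptor_only, "da", "aa", "a")
  b <- ratio_mean(acceptor_only, "dd", "aa", "b")
  cc <- ratio_mean(donor_only, "aa", "dd", "c")
  d <- ratio_mean(donor_only, "da", "dd", "d")

  bleedthrough_params(
    a = a[1], b = b[1], c = cc[1], d = d[1],
    n_pixels = c(a = a[2], b = b[2], c = cc[2], d = d[2])
  )
}

#' @describeIn estimate_bleedthrough Construct bleed-through parameters
#'   directly (e.g. from a published table).
#' @param a,b,c,d Nonnegative finite bleed-through fractions.
#' @param n_pixels Optional pixel counts behind each estimate.
#' @export
bleedthrough_params <- function(a, b, c, d, n_pixels = NULL) {
  vals <- c(a = a, b = b, c = c, d = d)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    abort("bleed-through parameters must be finite and nonnegative")
  }
  structure(
    list(a = a, b = b, c = c, d = d, n_pixels = n_pixels),
    class = "bleedthrough_params"
  )
}

#' @export
print.bleedthrough_params <- function(x, ...) {
  cat("<bleedthrough_params> a =", signif(x$a, 4),
      "b =", signif(x$b, 4), "c =", signif(x$c, 4),
      "d =", signif(x$d, 4), "\n")
  invisible(x)
}

#' @describeIn estimate_bleedthrough Parameters as a two-column tibble.
#' @param x A `bleedthrough_params` object.
#' @param ... Unused.
#' @export
tidy.bleedthrough_params <- function(x, ...) {
  tibble(
    parameter = c("a", "b", "c", "d"),
    value = c(x$a, x$b, x$c, x$d),
    n_pixels = if (is.null(x$n_pixels)) NA_real_ else as.numeric(x$n_pixels)
  )
}

#' Bleed-through-corrected FRET intensity (Fc)
#'
#' Subtracts the donor and acceptor contributions from the FRET-channel
#' image pixel by pixel. Two algebraic variants are supported:
#' \describe{
#'   \item{nested (default)}{\eqn{F_c = I_{DA} - a(I_{AA} - c I_{DD}) -
#'     d(I_{DD} - b I_{AA})}: each single-colour image is first corrected
#'     for the other fluorophore's spill before being scaled out of the
#'     FRET channel, following the classical three-cube correction.}
#'   \item{flat}{\eqn{F_c = I_{DA} - a I_{AA} - c I_{DD} - d I_{DD} -
#'     b I_{AA}}: every term subtracted directly.}
#' }
#' The two agree exactly whenever `b = c = 0`. Removed (masked) pixels stay
#' removed (`NA`). The variant used is recorded as an attribute on the
#' result.
#'
#' @param field A masked [image_field()].
#' @param params [bleedthrough_params()].
#' @param variant `"nested"` or `"flat"`.
#' @return Matrix of corrected FRET intensities with attribute `variant`.
#' @export
corrected_fret <- function(field, params, variant = c("nested", "flat")) {
  variant <- arg_match(variant)
  fc <- switch(variant,
    nested = field$da - params$a * (field$aa - params$c * field$dd) -
      params$d * (field$dd - params$b * field$aa),
    flat = field$da - params$a * field$aa - params$c * field$dd -
      params$d * field$dd - params$b * field$aa
  )
  fc[!field$valid] <- NA_real_
  attr(fc, "variant") <- variant
  fc
}

#' Pixel-wise NFRET for one field
#'
#' Normalizes the corrected FRET intensity to the square root of the product
#' of the acceptor and donor images, pixel by pixel:
#' \eqn{NFRET = F_c / \sqrt{I_{AA} I_{DD}}}. Pixels are defined only where
#' the field is valid, the product \eqn{I_{AA} I_{DD}} is strictly positive
#' and \eqn{F_c} is finite; the field mean averages the defined pixels.
#'
#' @param field A masked [image_field()].
#' @param fc Corrected FRET matrix from [corrected_fret()]; computed from
#'   `params` when omitted.
#' @param params,variant Used to compute `fc` when it is not supplied.
#' @return A `pixel_nfret` object: matrices `fc` and `nfret`, logical
#'   `defined` mask, `field_mean`, `n_defined`, labels and the variant.
#' @export
pixel_nfret <- function(field, fc = NULL, params = NULL,
                        variant = c("nested", "flat")) {
  if (is.null(fc)) {
    if (is.null(params)) abort("supply either fc or params")
    fc <- corrected_fret(field, params, variant)
  }
  if (!all(dim(fc) == dim(field$dd))) abort("fc shape mismatch with field")
  prod <- field$aa * field$dd
  defined <- field$valid & is.finite(fc) & prod > 0
  nfret <- matrix(NA_real_, nrow(fc), ncol(fc))
  nfret[defined] <- fc[defined] / sqrt(prod[defined])
  structure(
    list(
      fc = fc, nfret = nfret, defined = defined,
      field_mean = if (any(defined)) mean(nfret[defined]) else NA_real_,
      n_defined = sum(defined),
      field_id = field$field_id, sample_id = field$sample_id,
      variant = attr(fc, "variant") %||% "supplied"
    ),
    class = "pixel_nfret"
  )
}

#' @export
print.pixel_nfret <- function(x, ...) {
  cat("<pixel_nfret> field ", x$field_id, " | ", x$n_defined,
      " defined px | mean ", signif(x$field_mean, 4),
      " | variant ", x$variant, "\n", sep = "")
  invisible(x)
}

#' Pool pixel-NFRET results into a sample summary
#'
#' The sample mean pools the defined pixels of every field (equivalently,
#' the pixel-count-weighted mean of field means); the unweighted mean of
#' field means is reported alongside.
#'
#' @param results A `pixel_nfret` or list of them (one per field).
#' @return One-row tibble: `sample_mean` (pooled pixels),
#'   `mean_of_field_means`, `n_fields`, `n_pixels`.
#' @export
nfret_sample_summary <- function(results) {
  if (inherits(results, "pixel_nfret")) results <- list(results)
  field_means <- map_dbl(results, "field_mean")
  n_defined <- map_dbl(results, "n_defined")
  tibble(
    sample_mean = sum(field_means * n_defined) / sum(n_defined),
    mean_of_field_means = mean(field_means),
    n_fields = length(results),
    n_pixels = sum(n_defined)
  )
}

#' End-to-end pixel-FRET analysis of one sample
#'
#' Chains the image workflow: autofluorescence thresholds from vector-only
#' fields, masking of every field, bleed-through estimation from the
#' single-colour controls (unless parameters are supplied), corrected FRET
#' and pixel NFRET per sample field, and the pooled sample summary.
#'
#' @param sample_fields,vector_fields,donor_fields,acceptor_fields
#'   [image_field()]s or lists of them.
#' @param percentile Autofluorescence threshold percentile.
#' @param params Optional [bleedthrough_params()]; estimated when `NULL`.
#' @param variant Correction variant passed to [corrected_fret()].
#' @return An `image_fret_analysis` list: `thresholds`, `params`, per-field
#'   `results`, `summary` tibble and the `variant`.
#' @export
analyze_image_fret <- function(sample_fields, vector_fields, donor_fields,
                               acceptor_fields, percentile = 0.999,
                               params = NULL,
                               variant = c("nested", "flat")) {
  variant <- arg_match(variant)
  thresholds <- autofluorescence_thresholds(vector_fields, percentile)
  m <- function(fields) lapply(as_field_list(fields), mask_pixels, thresholds)
  if (is.null(params)) {
    params <- estimate_bleedthrough(m(donor_fields), m(acceptor_fields))
  }
  results <- lapply(m(sample_fields), function(f) {
    pixel_nfret(f, params = params, variant = variant)
  })
  structure(
    list(
      thresholds = thresholds, params = params, results = results,
      summary = nfret_sample_summary(results), variant = variant
    ),
    class = "image_fret_analysis"
  )
}

#' @export
print.image_fret_analysis <- function(x, ...) {
  cat("<image_fret_analysis> ", x$summary$n_fields, " fields | sample mean ",
      signif(x$summary$sample_mean, 4), " | variant ", x$variant, "\n",
      sep = "")
  invisible(x)
}
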