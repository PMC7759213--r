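# map a matrix onto palette RGB with masked pixels in a fixed colour;
# returns an H x W x 3 array in [0, 1]
matrix_to_rgb <- function(x, defined, limits, palette, mask_color) {
  lo <- limits[1]
  hi <- limits[2]
  scaled <- (x - lo) / (hi - lo)
  scaled[!is.finite(scaled)] <- 0
  idx <- 1L + as.integer(round(pmin(pmax(scaled, 0), 1) * (length(palette) - 1)))
  cols <- grDevices::col2rgb(palette)[, idx, drop = FALSE] / 255
  mask_rgb <- as.vector(grDevices::col2rgb(mask_color)) / 255
  arr <- array(0, dim = c(nrow(x), ncol(x), 3))
  for (k in 1:3) {
    plane <- matrix(cols[k, ], nrow(x), ncol(x))
    plane[!defined] <- mask_rgb[k]
    arr[, , k] <- plane
  }
  arr
}

#' Render corrected-FRET and NFRET heatmap images
#'
#' Writes the Fc and NFRET matrices of a [pixel_nfret()] result as PNG
#' heatmaps with a fixed colour scale; undefined (masked) pixels are drawn
#' in a distinct flat colour. Rendering is purely deterministic: the same
#' result produces byte-identical files. The scale bounds used are recorded
#' in the returned metadata.
#'
#' @param result A `pixel_nfret` object.
#' @param fc_path,nfret_path Output PNG paths (either may be `NULL` to
#'   skip).
#' @param fc_limits Colour-scale bounds for Fc; defaults to the observed
#'   range of defined pixels.
#' @param nfret_limits Colour-scale bounds for NFRET (default `c(0, 1)`).
#' @param palette Colour vector (default 256-step viridis).
#' @param mask_color Colour for masked pixels.
#' @return Invisibly, a list with the paths and scale bounds used.
#' @export
render_maps <- function(result, fc_path = NULL, nfret_path = NULL,
                        fc_limits = NULL, nfret_limits = c(0, 1),
                        palette = grDevices::hcl.colors(256, "viridis"),
                        mask_color = "#808080") {
  if (!inherits(result, "pixel_nfret")) {
    abort("result must be a pixel_nfret object")
  }
  fc_limits <- fc_limits %||% (
    if (any(result$defined)) range(result$fc[result$defined]) else c(0, 1)
  )
  if (diff(fc_limits) == 0) fc_limits <- fc_limits + c(-0.5, 0.5)
  meta <- list(fc_path = fc_path, nfret_path = nfret_path,
               fc_limits = fc_limits, nfret_limits = nfret_limits)
  if (!is.null(fc_path)) {
    png::writePNG(
      matrix_to_rgb(result$fc, result$defined, fc_limits, palette,
                    mask_color),
      fc_path
    )
  }
  if (!is.null(nfret_path)) {
    png::writePNG(
      matrix_to_rgb(result$nfret, result$defined, nfret_limits, palette,
                    mask_color),
      nfret_path
    )
  }
  invisible(meta)
}
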