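#' Three-channel microscopy field
#'
#' Container for one field of view of a sensitized-emission FRET experiment:
#' the DD (donor-excite/donor-emit), AA (acceptor-excite/acceptor-emit) and
#' DA (donor-excite/acceptor-emit) pixel matrices, the detector saturation
#' value, and a validity mask. Masks are carried as an explicit logical
#' matrix, never encoded as sentinel intensities; pixels are addressed
#' row-major.
#'
#' @param dd,aa,da Numeric matrices of identical shape.
#' @param saturation_value Intensity at which the detector saturates.
#' @param field_id,sample_id Labels.
#' @param valid Optional logical matrix; defaults to all-valid.
#' @return An `image_field` object.
#' @export
image_field <- function(dd, aa, da, saturation_value = 2^16 - 1,
                        field_id = NA_character_, sample_id = NA_character_,
                        valid = NULL) {
  if (!all(dim(dd) == dim(aa)) || !all(dim(dd) == dim(da))) {
    abort("dd, aa and da must have identical shapes")
  }
  valid <- valid %||% matrix(TRUE, nrow(dd), ncol(dd))
  if (!all(dim(valid) == dim(dd))) abort("valid mask shape mismatch")
  structure(
    list(
      dd = dd, aa = aa, da = da, valid = valid,
      saturation_value = saturation_value,
      field_id = field_id, sample_id = sample_id,
      masked = FALSE
    ),
    class = "image_field"
  )
}

#' @export
print.image_field <- function(x, ...) {
  cat("<image_field> ", nrow(x$dd), "x", ncol(x$dd),
      " | sat ", x$saturation_value,
      " | ", sum(x$valid), "/", length(x$valid), " valid",
      if (x$masked) " | masked" else "", "\n", sep = "")
  invisible(x)
}

as_field_list <- function(fields) {
  if (inherits(fields, "image_field")) list(fields) else fields
}

#' Write / read an image field as per-channel TIFF files
#'
#' Files follow the `_DD.tif` / `_AA.tif` / `_DA.tif` suffix convention.
#' Intensities are stored as 16-bit samples scaled by the field's
#' saturation value.
#'
#' @param field An [image_field()].
#' @param prefix Path prefix; suffixes are appended.
#' @return `write_image_field` returns the three paths invisibly;
#'   `read_image_field` returns an [image_field()].
#' @export
write_image_field <- function(field, prefix) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    abort("the 'tiff' package is required for TIFF I/O")
  }
  paths <- paste0(prefix, c("_DD.tif", "_AA.tif", "_DA.tif"))
  chans <- list(field$dd, field$aa, field$da)
  for (i in 1:3) {
    tiff::writeTIFF(
      pmin(pmax(chans[[i]] / field$saturation_value, 0), 1),
      paths[i], bits.per.sample = 16
    )
  }
  invisible(paths)
}

#' @rdname write_image_field
#' @param saturation_value Saturation value used to rescale stored samples.
#' @param field_id,sample_id Labels for the returned field.
#' @export
read_image_field <- function(prefix, saturation_value = 2^16 - 1,
                             field_id = NA_character_,
                             sample_id = NA_character_) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    abort("the 'tiff' package is required for TIFF I/O")
  }
  paths <- paste0(prefix, c("_DD.tif", "_AA.tif", "_DA.tif"))
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    abort(paste("missing channel files:", paste(missing, collapse = ", ")))
  }
  chans <- lapply(paths, function(p) {
    round(tiff::readTIFF(p) * saturation_value)
  })
  image_field(chans[[1]], chans[[2]], chans[[3]],
              saturation_value = saturation_value,
              field_id = field_id, sample_id = sample_id)
}

#' Simulate one microscopy field with known ground truth
#'
#' Places non-overlapping disk-shaped cells on a lognormal background. Each
#' cell's donor/acceptor/complex amounts are drawn exactly as in
#' [simulate_flow_sample()]; the clean channel sources are mixed through the
#' configured bleed-through coefficients (acceptor into DD with `b`, donor
#' into AA with `c`, acceptor and donor into DA with `a` and `d`), the
#' background added, per-pixel multiplicative noise applied, and pixels
#' clipped to `2^image_bit_depth - 1` (and rounded to integers when
#' `config$quantize`). No optics beyond flat disks is modelled: no PSF,
#' no illumination falloff.
#'
#' @param config A [sim_config()].
#' @param n_cells Number of cells to place; defaults to
#'   `config$n_cells_field`.
#' @param field_id,sample_id Labels.
#' @param dimer_fraction,efficiency Optional overrides as in
#'   [simulate_flow_sample()].
#' @param max_tries Bound on placement attempts before erroring.
#' @return A list of class `image_sim`: `field` (an [image_field()]),
#'   `truth` (list with per-cell tibble `cells`, the pixel label matrix
#'   `label`, and the clean per-pixel `sensitized` source matrix).
#' @export
simulate_image_field <- function(config, n_cells = config$n_cells_field,
                                 field_id = "field_1",
                                 sample_id = "sample",
                                 dimer_fraction = NULL, efficiency = NULL,
                                 max_tries = 200L * max(n_cells, 1L)) {
  shape <- config$image_shape
  r <- config$cell_radius_px
  if (any(shape < 2 * r)) {
    abort("image_shape must be at least one cell diameter")
  }
  sat <- 2^config$image_bit_depth - 1
  with_seed(config$seed, {
    # rejection-sample non-overlapping disk centres
    centres <- matrix(numeric(0), ncol = 2)
    tries <- 0L
    while (nrow(centres) < n_cells) {
      tries <- tries + 1L
      if (tries > max_tries) {
        abort("could not place all cells without overlap; reduce n_cells")
      }
      cand <- c(runif(1, r + 1, shape[1] - r), runif(1, r + 1, shape[2] - r))
      if (nrow(centres) == 0 ||
          all((centres[, 1] - cand[1])^2 + (centres[, 2] - cand[2])^2 >=
              (2 * r)^2)) {
        centres <- rbind(centres, cand)
      }
    }

    truth <- draw_cell_truth(config, max(n_cells, 0L),
                             dimer_fraction, efficiency)
    sources <- source_matrix(truth)

    label <- matrix(0L, shape[1], shape[2])
    src_maps <- list(
      donor = matrix(0, shape[1], shape[2]),
      acceptor = matrix(0, shape[1], shape[2]),
      sensitized = matrix(0, shape[1], shape[2])
    )
    if (n_cells > 0) {
      row_idx <- row(label)
      col_idx <- col(label)
      for (i in seq_len(n_cells)) {
        inside <- (row_idx - centres[i, 1])^2 +
          (col_idx - centres[i, 2])^2 <= r^2
        label[inside] <- i
        for (s in names(src_maps)) {
          src_maps[[s]][inside] <- sources[i, s]
        }
      }
    }

    co <- config$mixing$coefficients %||% c(a = 0, b = 0, c = 0, d = 0)
    clean <- list(
      dd = src_maps$donor + co[["b"]] * src_maps$acceptor,
      aa = src_maps$acceptor + co[["c"]] * src_maps$donor,
      da = src_maps$sensitized + co[["a"]] * src_maps$acceptor +
        co[["d"]] * src_maps$donor
    )
    npx <- prod(shape)
    observed <- lapply(clean, function(x) {
      bg <- matrix(rlnorm(npx, config$bg_mu, config$bg_sigma),
                   shape[1], shape[2])
      noise <- matrix(noise_factor(npx, config$noise_cv),
                      shape[1], shape[2])
      y <- pmin((x + bg) * noise, sat)
      if (config$quantize) round(y) else y
    })

    cells <- truth
    if (n_cells > 0) {
      cells$row <- centres[, 1]
      cells$col <- centres[, 2]
      cells$cell <- seq_len(n_cells)
    }
    structure(
      list(
        field = image_field(observed$dd, observed$aa, observed$da,
                            saturation_value = sat,
                            field_id = field_id, sample_id = sample_id),
        truth = list(
          cells = cells, label = label,
          sensitized = src_maps$sensitized
        )
      ),
      class = "image_sim"
    )
  })
}

#' Simulate a set of fields for one sample
#'
#' Convenience wrapper producing `n_fields` independent fields (sub-seeded
#' from `config$seed`), mirroring the multi-field acquisitions the
#' pixel-level workflow pools over.
#'
#' @inheritParams simulate_image_field
#' @param n_fields Number of fields of view.
#' @return List of `image_sim` objects.
#' @export
simulate_image_fields <- function(config, n_fields = 10L,
                                  sample_id = "sample",
                                  dimer_fraction = NULL, efficiency = NULL) {
  lapply(seq_len(n_fields), function(i) {
    cfg <- config
    cfg$seed <- config$seed + 1000L + i
    simulate_image_field(cfg, field_id = paste0("field_", i),
                         sample_id = sample_id,
                         dimer_fraction = dimer_fraction,
                         efficiency = efficiency)
  })
}
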