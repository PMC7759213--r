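make_field <- function(dd, aa, da, sat = 2^16 - 1) {
  image_field(dd, aa, da, saturation_value = sat)
}

test_that("autofluorescence thresholds pool pixels across fields", {
  const <- matrix(5, 10, 10)
  f <- make_field(const, const, const)
  thr <- autofluorescence_thresholds(f, 0.999)
  expect_equal(unname(thr), c(5, 5, 5))

  m <- matrix(as.numeric(1:1000), 25, 40)
  f2 <- make_field(m, m, m)
  expect_equal(unname(autofluorescence_thresholds(f2, 0.999)["dd"]), 999.001)

  # two fields with disjoint ranges: the pooled quantile, not a mean of
  # per-field statistics
  lo <- make_field(matrix(1, 10, 10), matrix(1, 10, 10), matrix(1, 10, 10))
  hi <- make_field(matrix(101, 10, 10), matrix(101, 10, 10),
                   matrix(101, 10, 10))
  thr2 <- autofluorescence_thresholds(list(lo, hi), 0.5)
  expect_equal(unname(thr2["dd"]),
               quantile(c(rep(1, 100), rep(101, 100)), 0.5, names = FALSE))

  expect_error(autofluorescence_thresholds(list(), 0.999), "at least one")
  expect_error(autofluorescence_thresholds(f, 1), "strictly between")
})

test_that("masking zeroes sub-threshold pixels and removes saturated ones", {
  dd <- matrix(c(1, 2, 3, 255), 2, 2)
  f <- make_field(dd, dd, dd, sat = 255)
  masked <- mask_pixels(f, c(dd = 2.5, aa = 2.5, da = 2.5))
  expect_equal(masked$dd[, 1], c(0, 0))
  expect_equal(masked$dd[1, 2], 3)
  expect_false(masked$valid[2, 2]) # saturated pixel removed
  expect_true(masked$masked)

  # threshold 0 changes nothing except saturated pixels
  m0 <- mask_pixels(f, c(dd = 0, aa = 0, da = 0))
  expect_equal(m0$dd, dd)
  expect_identical(sum(!m0$valid), 1L)

  # an all-background field masks to zero everywhere
  bg <- make_field(matrix(1, 5, 5), matrix(1, 5, 5), matrix(1, 5, 5))
  mb <- mask_pixels(bg, c(dd = 10, aa = 10, da = 10))
  expect_true(all(mb$dd == 0) && all(mb$aa == 0) && all(mb$da == 0))
})

test_that("bleed-through parameters are pixel-ratio means with exclusions", {
  # constant-ratio acceptor-only field: a = 0.12 exactly
  aa <- matrix(rlnorm(400, 5, 1), 20, 20)
  acc <- make_field(0.02 * aa, aa, 0.12 * aa)
  don_dd <- matrix(rlnorm(400, 5, 1), 20, 20)
  don <- make_field(don_dd, 0.05 * don_dd, 0.4 * don_dd)
  p <- estimate_bleedthrough(don, acc)
  expect_equal(p$a, 0.12, tolerance = 1e-12)
  expect_equal(p$b, 0.02, tolerance = 1e-12)
  expect_equal(p$c, 0.05, tolerance = 1e-12)
  expect_equal(p$d, 0.40, tolerance = 1e-12)

  # zero-denominator pixels are excluded rather than poisoning the mean
  aa2 <- aa
  aa2[1, 1] <- 0
  acc2 <- make_field(0.02 * aa2, aa2, 0.12 * aa2)
  p2 <- estimate_bleedthrough(don, acc2)
  expect_equal(p2$a, 0.12, tolerance = 1e-12)

  # all denominators zero -> error
  zeros <- make_field(matrix(0, 4, 4), matrix(0, 4, 4), matrix(0, 4, 4))
  expect_error(estimate_bleedthrough(don, zeros), "no valid pixels")
})

test_that("bleed-through recovery from masked synthetic fields is exact at zero noise", {
  don_cfg <- quiet_cfg(seed = 71, image_shape = c(96, 96), n_cells_field = 8,
                       acceptor_rate = 0,
                       dimer_fraction_vehicle = 0, dimer_fraction_max = 0,
                       mixing = spillover_matrix(a = 0.15, b = 0.02,
                                                 c = 0.05, d = 0.40))
  acc_cfg <- modifyList_cfg(don_cfg, list(acceptor_rate = 1.5, donor_rate = 0))
  thr <- c(dd = 0, aa = 0, da = 0)
  don <- lapply(image_fields_for(don_cfg, 2), mask_pixels, thr)
  acc <- lapply(image_fields_for(acc_cfg, 2), mask_pixels, thr)
  p <- estimate_bleedthrough(don, acc)
  expect_equal(c(p$a, p$b, p$c, p$d), c(0.15, 0.02, 0.05, 0.40),
               tolerance = 1e-9)
})

test_that("corrected FRET variants behave and round-trip the generator", {
  dd <- matrix(rlnorm(100, 4, 1), 10, 10)
  aa <- matrix(rlnorm(100, 4, 1), 10, 10)
  da <- matrix(rlnorm(100, 4, 1), 10, 10)
  f <- make_field(dd, aa, da)

  p0 <- bleedthrough_params(0, 0, 0, 0)
  expect_equal(unclass_attr(corrected_fret(f, p0, "nested")), da)
  expect_equal(unclass_attr(corrected_fret(f, p0, "flat")), da)

  # with b = c = 0 the two parenthesizations coincide exactly
  p1 <- bleedthrough_params(a = 0.3, b = 0, c = 0, d = 0.2)
  expect_identical(unclass_attr(corrected_fret(f, p1, "nested")),
                   unclass_attr(corrected_fret(f, p1, "flat")))
  expect_error(corrected_fret(f, p1, "sideways"))

  # noiseless synthetic field: nested correction with the true parameters
  # recovers the generator's sensitized source pixel for pixel (exactly
  # when b*c = 0; to O(b*c) under full four-coefficient mixing, since the
  # nested form omits the 1/(1 - bc) of the exact unmix)
  cfg <- quiet_cfg(seed = 72, image_shape = c(96, 96), n_cells_field = 8,
                   ligand_dose = 100, ecd_distance = 30,
                   mixing = spillover_matrix(a = 0.15, b = 0,
                                             c = 0.05, d = 0.40))
  sim <- simulate_image_field(cfg)
  masked <- mask_pixels(sim$field, c(dd = 0, aa = 0, da = 0))
  fc <- corrected_fret(masked, bleedthrough_params(0.15, 0, 0.05, 0.40),
                       "nested")
  ok <- masked$valid # saturated-cell pixels are removed, hence NA in fc
  expect_equal(as.vector(fc[ok]), as.vector(sim$truth$sensitized[ok]),
               tolerance = 1e-9)

  cfg_full <- modifyList_cfg(
    cfg, list(mixing = spillover_matrix(a = 0.15, b = 0.02,
                                        c = 0.05, d = 0.40))
  )
  sim2 <- simulate_image_field(cfg_full)
  masked2 <- mask_pixels(sim2$field, c(dd = 0, aa = 0, da = 0))
  fc2 <- corrected_fret(masked2,
                        bleedthrough_params(0.15, 0.02, 0.05, 0.40),
                        "nested")
  on_cell <- sim2$truth$sensitized > 0 & masked2$valid
  expect_lt(
    max(abs(fc2[on_cell] / sim2$truth$sensitized[on_cell] - 1)),
    0.002
  )
})

test_that("pixel NFRET masks undefined pixels and pools consistently", {
  dd <- matrix(c(4, 0, 9), 1, 3)
  aa <- matrix(c(9, 5, 4), 1, 3)
  da <- matrix(c(6, 1, 12), 1, 3)
  f <- make_field(dd, aa, da)
  res <- pixel_nfret(f, fc = da)
  expect_equal(res$nfret[1, 1], 1)          # 6 / sqrt(36)
  expect_true(is.na(res$nfret[1, 2]))       # dd = 0 pixel masked
  expect_equal(res$nfret[1, 3], 2)
  expect_equal(res$field_mean, 1.5)
  expect_identical(res$n_defined, 2L)

  # sample mean equals the pixel-count-weighted mean of field means
  f2 <- make_field(matrix(4, 2, 2), matrix(9, 2, 2), matrix(3, 2, 2))
  res2 <- pixel_nfret(f2, fc = matrix(3, 2, 2))
  s <- nfret_sample_summary(list(res, res2))
  expect_equal(s$sample_mean,
               (res$field_mean * 2 + res2$field_mean * 4) / 6)
  expect_equal(s$mean_of_field_means, mean(c(1.5, 0.5)))
  expect_identical(s$n_pixels, 6)
})

test_that("the flow and image NFRET paths agree when b = c = 0", {
  mix <- spillover_matrix(a = 0.15, b = 0, c = 0, d = 0.40)
  cfg <- sim_config(seed = 73, image_shape = c(96, 96), n_cells_field = 8,
                    ligand_dose = 100, mixing = mix, quantize = FALSE)
  sim <- simulate_image_field(cfg)
  masked <- mask_pixels(sim$field, c(dd = 10, aa = 10, da = 10))
  res <- pixel_nfret(masked, params = bleedthrough_params(0.15, 0, 0, 0.40))
  idx <- which(res$defined)
  events <- tibble::tibble(
    `Pacific Blue` = masked$dd[idx],
    FITC = masked$aa[idx],
    AmCyan = masked$da[idx]
  )
  flow <- nfret_per_cell(compensate(events, mix))
  expect_true(all(flow$nfret_defined))
  expect_lt(max(abs(flow$nfret - res$nfret[idx])), 1e-9)
})

test_that("image fields round-trip through per-channel TIFF files", {
  cfg <- quiet_cfg(seed = 81, image_shape = c(48, 48), n_cells_field = 2,
                   quantize = TRUE)
  sim <- simulate_image_field(cfg)
  prefix <- file.path(withr::local_tempdir(), "field_1")
  paths <- write_image_field(sim$field, prefix)
  expect_true(all(file.exists(paths)))
  back <- read_image_field(prefix, saturation_value = 2^16 - 1)
  expect_equal(back$dd, sim$field$dd)
  expect_equal(back$aa, sim$field$aa)
  expect_equal(back$da, sim$field$da)
  expect_error(read_image_field(file.path(tempdir(), "nope")), "missing")
})

test_that("rendered maps are deterministic and mark masked pixels", {
  f <- make_field(matrix(4, 4, 4), matrix(9, 4, 4), matrix(6, 4, 4))
  f$valid[1, 1] <- FALSE
  res <- pixel_nfret(f, fc = f$da)
  p1 <- withr::local_tempfile(fileext = ".png")
  p2 <- withr::local_tempfile(fileext = ".png")
  render_maps(res, fc_path = p1, nfret_path = p2)
  img <- png::readPNG(p2)
  expect_equal(img[1, 1, ], rep(128 / 255, 3), tolerance = 1e-6)

  p3 <- withr::local_tempfile(fileext = ".png")
  render_maps(res, nfret_path = p3)
  expect_identical(readBin(p2, "raw", file.size(p2)),
                   readBin(p3, "raw", file.size(p3)))

  # fully masked result renders as a uniform mask-colour image
  f2 <- f
  f2$valid[] <- FALSE
  res2 <- pixel_nfret(f2, fc = f2$da)
  p4 <- withr::local_tempfile(fileext = ".png")
  render_maps(res2, nfret_path = p4)
  img2 <- png::readPNG(p4)
  expect_true(all(abs(img2 - 128 / 255) < 1e-6))
})
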