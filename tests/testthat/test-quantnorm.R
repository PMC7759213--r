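test_that("bead subpopulations are identified by deterministic 1-D k-means", {
  beads <- simulate_bead_set(c(10, 100, 1000), true_slope = 2, cv = 0,
                             n_per_subpop = 20, seed = 3)
  expect_equal(identify_bead_subpops(beads, 3), c(20, 200, 2000),
               tolerance = 1e-12)

  vals <- c(1, 2, 4, 8, 16, 32) * 250
  b6 <- simulate_bead_set(vals, true_slope = 1.8, cv = 0.05,
                          n_per_subpop = 500, seed = 4)
  means <- identify_bead_subpops(b6, 6)
  expect_lt(max(abs(means / (1.8 * vals) - 1)), 0.02)

  # k = 1 degenerates to the global mean
  expect_equal(identify_bead_subpops(b6, 1), mean(b6$mfi))

  expect_error(identify_bead_subpops(beads[1:20, ], 3), "at least 10")
  const <- tibble::tibble(mfi = rep(5, 100))
  expect_error(identify_bead_subpops(const, 3), "fewer than")
})

test_that("the bead slope is an origin-constrained least-squares fit", {
  cal <- fit_bead_slope(c(20, 200, 2000), c(10, 100, 1000))
  expect_equal(cal$slope, 2)
  expect_equal(cal$slope_se, 0)

  expect_equal(fit_bead_slope(6, 3)$slope, 2)

  # round trip: noiseless beads -> identified subpops -> slope recovery
  vals <- c(1, 2, 4, 8, 16, 32) * 100
  beads <- simulate_bead_set(vals, true_slope = 2.5, cv = 0,
                             n_per_subpop = 50, seed = 5)
  cal2 <- fit_bead_slope(identify_bead_subpops(beads, 6), vals)
  expect_equal(cal2$slope, 2.5, tolerance = 1e-12)

  expect_error(fit_bead_slope(c(1, 2), c(0, 0)), "zero")
  expect_error(fit_bead_slope(c(1, 2), 1), "same length")

  # conversion subtracts background before dividing by the slope
  expect_equal(mfi_to_mefl(210, cal, background = 10), 100)
})

test_that("reporter summaries convert, normalize and propagate error", {
  cal <- fit_bead_slope(c(10, 100), c(10, 100)) # slope 1, se 0
  data <- tibble::tibble(
    treatment = rep(c("ligand", "vehicle"), each = 3),
    replicate = rep(1:3, 2),
    mfi = c(300, 300, 300, 100, 100, 100)
  )
  rs <- reporter_summary(data, autofluorescence = c(0, 0, 0), cal)
  expect_equal(rs$fold$fold, 3)
  expect_equal(rs$fold$fold_se, 0)

  # vehicle arm fully explained by autofluorescence -> undefined fold
  rs2 <- reporter_summary(data, autofluorescence = c(100, 100, 100), cal)
  expect_false(rs2$fold$fold_defined)

  # hand-propagated SEs: arms (300 +/- 30, 100 +/- 10), slope exact
  d3 <- tibble::tibble(
    treatment = rep(c("ligand", "vehicle"), each = 3),
    replicate = rep(1:3, 2),
    mfi = c(300 + c(-1, 0, 1) * sqrt(3) * 30, 100 + c(-1, 0, 1) * sqrt(3) * 10)
  )
  rs3 <- reporter_summary(d3, autofluorescence = 0, cal)
  expect_equal(rs3$fold$fold, 3)
  expect_equal(rs3$fold$fold_se, 3 * sqrt(0.01 + 0.01), tolerance = 1e-9)
})

test_that("luciferase normalization anchors the reporter-only condition at 1", {
  plate <- tibble::tibble(
    condition = rep(c("vector", "reporter", "test"), each = 3),
    well = rep(c("A1", "B1", "C1"), each = 3),
    firefly = c(0, 0, 0, 900, 1000, 1100, 4500, 5000, 5500),
    renilla = c(0, 0, 0, 90, 100, 110, 90, 100, 110)
  )
  out <- luciferase_normalize(plate)
  rep_mean <- mean(out$normalized[out$condition == "reporter"], na.rm = TRUE)
  expect_equal(rep_mean, 1)
  expect_equal(out$normalized[out$condition == "test"], 5)
  expect_false(any(out$valid[out$condition == "vector"]))

  # a well identical to the background reads zero after subtraction
  plate2 <- tibble::tibble(
    condition = rep(c("vector", "reporter", "blanklike"), each = 3),
    well = rep(c("A1", "B1", "C1"), each = 3),
    firefly = c(50, 50, 50, 950, 1050, 1150, 50, 50, 50),
    renilla = c(10, 10, 10, 100, 110, 120, 60, 60, 60)
  )
  out2 <- luciferase_normalize(plate2)
  expect_equal(out2$firefly_bg[out2$condition == "blanklike"], 0)
  expect_equal(out2$normalized[out2$condition == "blanklike"], 0)

  # idempotence on data that is already normalized (background 0,
  # reporter-only mean 1)
  plate3 <- tibble::tibble(
    condition = rep(c("vector", "reporter", "test"), each = 3),
    well = rep(c("A1", "B1", "C1"), each = 3),
    firefly = c(0, 0, 0, 1, 1, 1, 7, 7, 7),
    renilla = c(0, 0, 0, 1, 1, 1, 1, 1, 1)
  )
  once <- luciferase_normalize(plate3)
  expect_equal(once$normalized[once$condition == "test"], 7)
  plate4 <- plate3
  plate4$firefly <- once$normalized[match(plate4$well, once$well)]
  plate4$firefly[plate4$condition == "vector"] <- 0
  plate4$renilla <- ifelse(plate4$condition == "vector", 0, 1)
  twice <- luciferase_normalize(plate4)
  expect_equal(twice$normalized[twice$condition == "test"], 7)

  expect_error(luciferase_normalize(plate[plate$condition != "vector", ]),
               "vector")
})

test_that("technical-replicate example reproduces the hand computation", {
  # firefly (900, 1000, 1100), renilla (90, 100, 110), no autoluminescence,
  # reporter-only mean ratio 10 -> normalized exactly 1
  plate <- tibble::tibble(
    condition = c(rep("vector", 3), rep("reporter", 3), rep("test", 3)),
    well = rep(c("V1", "R1", "T1"), each = 3),
    firefly = c(0, 0, 0, 1000, 1000, 1000, 900, 1000, 1100),
    renilla = c(0, 0, 0, 100, 100, 100, 90, 100, 110)
  )
  out <- luciferase_normalize(plate)
  expect_equal(out$ratio[out$well == "T1"], 10)
  expect_equal(out$normalized[out$well == "T1"], 1)
})

test_that("western normalization is exposure-gain invariant and control-referenced", {
  bands <- tidyr::expand_grid(exposure = c("e1", "e2"),
                              lane = c("ctrl", "test"))
  bands$mesa <- c(100, 200, 300, 600)    # e2 is a 3x / arbitrary-gain repeat
  bands$nanoluc <- c(50, 50, 150, 150)
  out <- western_normalize(bands, control_lane = "ctrl")
  expect_equal(out$relative_expression[out$lane == "ctrl"], 1)

  # doubling all intensities of one exposure changes nothing
  bands2 <- bands
  bands2$mesa[bands2$exposure == "e2"] <- bands2$mesa[bands2$exposure == "e2"] * 7
  bands2$nanoluc[bands2$exposure == "e2"] <-
    bands2$nanoluc[bands2$exposure == "e2"] * 7
  out2 <- western_normalize(bands2, control_lane = "ctrl")
  expect_identical(out$relative_expression, out2$relative_expression)

  # identical lanes -> relative expression 1 for both
  same <- tidyr::expand_grid(exposure = c("e1", "e2"),
                             lane = c("ctrl", "test"))
  same$mesa <- c(100, 100, 300, 300)
  same$nanoluc <- c(40, 40, 120, 120)
  out3 <- western_normalize(same, control_lane = "ctrl")
  expect_equal(out3$relative_expression, c(1, 1))

  # control ratio 0.5, test ratio 1.0 -> relative 2, dose factor 0.5
  r <- tibble::tibble(
    exposure = "e1", lane = c("ctrl", "test"),
    mesa = c(25, 50), nanoluc = c(50, 50)
  )
  out4 <- western_normalize(r, control_lane = "ctrl")
  expect_equal(out4$relative_expression[out4$lane == "test"], 2)
  expect_equal(out4$dose_factor[out4$lane == "test"], 0.5)

  # a flagged (saturated) exposure is excluded for that lane only
  fl <- tidyr::expand_grid(exposure = c("e1", "e2"),
                           lane = c("ctrl", "a", "b"))
  fl$mesa <- c(100, 200, 300, 100, 200, 9999)
  fl$nanoluc <- c(50, 100, 150, 50, 100, 150)
  fl$mesa_ok <- c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE)
  out5 <- western_normalize(fl, control_lane = "ctrl")
  # lane b's mesa percent comes from e1 alone
  expect_equal(out5$mesa_pct[out5$lane == "b"], 100 * 300 / 600)

  expect_error(western_normalize(r, control_lane = "nope"), "not in")
})

test_that("the distance regression recovers exact and degenerate fits", {
  x <- c(8, 22, 35, 50)
  pts <- tibble::tibble(distance = x, fold = -0.027 * x + 2.9)
  fit <- distance_regression(pts)
  expect_equal(fit$slope, -0.027, tolerance = 1e-12)
  expect_equal(fit$intercept, 2.9, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)

  flat <- tibble::tibble(distance = x, fold = rep(2, 4))
  ffit <- distance_regression(flat)
  expect_equal(ffit$slope, 0)
  expect_equal(ffit$r_squared, 0)

  expect_error(distance_regression(pts[1:2, ]), "three points")
  expect_error(
    distance_regression(tibble::tibble(distance = c(1, 1, 1),
                                       fold = c(1, 2, 3))),
    "identical"
  )

  td <- tidy(fit)
  expect_equal(td$estimate[td$term == "distance"], -0.027, tolerance = 1e-12)
  expect_equal(glance(fit)$nobs, 4)
})

test_that("delta-method fold SE agrees with a parametric bootstrap", {
  mu_l <- 0.5
  mu_v <- 0.2
  cv <- 0.1
  fd <- fold_difference(mu_l, mu_v, cv * mu_l, cv * mu_v)
  boot <- withr::with_seed(99, {
    l <- rnorm(10000, mu_l, cv * mu_l)
    v <- rnorm(10000, mu_v, cv * mu_v)
    sd(l / v)
  })
  expect_lt(abs(fd$fold_se / boot - 1), 0.10)
})
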