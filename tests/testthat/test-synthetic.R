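test_that("release generator evaluates each model law exactly when noiseless", {
  # direct evaluation of the power law at t = 125
  tr <- kinetic_truth("korsmeyer_peppas", c(k = 0.05, n = 0.5),
                      noise_sd = 0)
  cv <- simulate_release_curve(tr)
  expect_equal(cv$fraction_released[cv$time_min == 125],
               0.05 * sqrt(125), tolerance = 1e-12)

  # two-term model with a negative relaxation coefficient
  tr2 <- kinetic_truth("peppas_sahlin",
                       list(k1 = 1.0697e-2, k2 = -0.2190e-3, m = 0.43),
                       noise_sd = 0)
  cv2 <- simulate_release_curve(tr2)
  t <- cv2$time_min
  expect_equal(cv2$fraction_released,
               pmax(0, 1.0697e-2 * t^0.43 - 0.2190e-3 * t^0.86),
               tolerance = 1e-12)

  # predictions are clipped into [0, 1] before noise
  tr3 <- kinetic_truth("zero_order", c(k = 0.01), noise_sd = 0)
  cv3 <- simulate_release_curve(tr3)
  expect_true(all(cv3$fraction_released <= 1))
})

test_that("generators are deterministic in the seed and vary across seeds", {
  tr <- function(seed) kinetic_truth("korsmeyer_peppas",
                                     c(k = 0.05, n = 0.5),
                                     noise_sd = 0.02, seed = seed)
  expect_identical(simulate_release_curve(tr(7)),
                   simulate_release_curve(tr(7)))
  expect_false(identical(simulate_release_curve(tr(7))$fraction_released,
                         simulate_release_curve(tr(8))$fraction_released))

  sp <- bead_phantom_spec(seed = 11)
  expect_identical(simulate_bead_image(sp), simulate_bead_image(sp))
  sp2 <- bead_phantom_spec(seed = 12)
  expect_false(identical(simulate_bead_image(sp)$image,
                         simulate_bead_image(sp2)$image))

  ft <- factorial_truth(list(area = c(5, 1, 1, -1, -1, 0.5)),
                        noise_sd = 0.3, seed = 3)
  expect_identical(simulate_factorial_experiment(ft),
                   simulate_factorial_experiment(ft))
})

test_that("release generator validates model parameters and timepoints", {
  expect_error(kinetic_truth("weibull", c(k = 1)), "arg")
  expect_error(kinetic_truth("korsmeyer_peppas", c(k = 0.05)),
               "requires parameter")
  expect_error(simulate_release_curve(
    kinetic_truth("zero_order", c(k = 1e-3)),
    timepoints = c(5, 5, 10)), "strictly increasing")
  expect_error(simulate_release_curve(
    kinetic_truth("zero_order", c(k = 1e-3)),
    timepoints = c(-5, 10)), "after 0")
})

test_that("logistic growth generator honours its limits", {
  # zero growth: constant at n0
  tr0 <- growth_truth(n0 = 0.3, capacity = 1.34, mu = 0, noise_sd = 0)
  g0 <- simulate_growth_curve(tr0, 0:10)
  expect_equal(g0$density, rep(0.3, 11), tolerance = 1e-12)

  # defaults reach >= 95% of capacity by 12 h, monotonically
  trd <- growth_truth(noise_sd = 0)
  gd <- simulate_growth_curve(trd, seq(0, 24, 0.5))
  d12 <- gd$density[gd$time == 12]
  expect_gt(d12, 0.95 * 1.34)
  expect_true(all(diff(gd$density) >= 0))
  expect_lt(max(gd$density), 1.34 + 1e-9)
})

test_that("digestion pair conserves cells and reports crossing truth", {
  # no growth, no death: medium + inbead == total everywhere
  tr <- kinetic_truth("korsmeyer_peppas", c(k = 0.04386, n = 0.5),
                      noise_sd = 0)
  pair <- simulate_digestion_pair(1e8, tr, cfu_noise_sd_log10 = 0)
  expect_equal(pair$noiseless$cfu_medium + pair$noiseless$cfu_inbead,
               rep(1e8, 15), tolerance = 1e-9)

  # release reaching 1 with zero growth/death must cross
  tr_full <- kinetic_truth("zero_order", c(k = 1 / 100), noise_sd = 0)
  p2 <- simulate_digestion_pair(1e8, tr_full, cfu_noise_sd_log10 = 0)
  expect_false(is.na(p2$crossing_min))
  expect_equal(p2$crossing_min, 50, tolerance = 0.01) # f = 0.5 at 50 min

  # release capped at 0.3 with strong in-bead growth: no crossing
  tr_cap <- kinetic_truth("peppas_sahlin",
                          list(k1 = 0.3 / 250^0.43, k2 = 0, m = 0.43),
                          noise_sd = 0)
  p3 <- simulate_digestion_pair(
    1e8, tr_cap, inbead_growth = growth_truth(mu = 0.6),
    cfu_noise_sd_log10 = 0)
  expect_true(is.na(p3$crossing_min))

  # constructed crossing at 130 min: f = 0.5 at t = 130 with G = 1
  k130 <- 0.5 / 130^0.5
  p4 <- simulate_digestion_pair(
    1e8, kinetic_truth("korsmeyer_peppas", c(k = k130, n = 0.5),
                       noise_sd = 0), cfu_noise_sd_log10 = 0)
  expect_equal(p4$crossing_min, 130, tolerance = 0.5)

  # missing phase in the death-rate map is an error
  expect_error(simulate_digestion_pair(
    1e8, tr, death_rate_per_phase = c(oral = 0, gastric = 0)),
    "missing phase")
})

test_that("factorial generator reproduces its quadratic surface", {
  # noiseless: replicates equal the surface value exactly
  b <- c(5.4, 0.3, 0.8, -0.5, -0.2, 0.15)
  ft <- factorial_truth(list(area = b), replicate_count = 3, noise_sd = 0)
  dat <- simulate_factorial_experiment(ft)
  expect_equal(nrow(dat), 27)
  coded <- code_levels(dat$agavin_pct, dat$whey_pct)
  expected <- b[1] + b[2] * coded$a + b[3] * coded$w + b[4] * coded$a^2 +
    b[5] * coded$w^2 + b[6] * coded$a * coded$w
  expect_equal(dat$value, expected, tolerance = 1e-12)

  # constant surface
  ftc <- factorial_truth(list(ee = c(96.77, 0, 0, 0, 0, 0)), noise_sd = 0)
  expect_true(all(simulate_factorial_experiment(ftc)$value == 96.77))

  # surface with maximum at (5, 3.75): that treatment has largest mean
  # coded optimum (1, 0): y = -(a-1)^2 - w^2 -> b = (.. ) on coded units
  ftm <- factorial_truth(list(r = c(-1, 2, 0, -1, -1, 0)), noise_sd = 0)
  dm <- simulate_factorial_experiment(ftm)
  means <- tapply(dm$value, dm$treatment, mean)
  best <- names(which.max(means))
  grid <- factorial_design_grid()
  expect_equal(grid$agavin_pct[grid$treatment == best], 5)
  expect_equal(grid$whey_pct[grid$treatment == best], 3.75)
})

test_that("bead phantom ground truth matches its construction", {
  # perfect disc: area within 2% of pi r^2, circularity ~ 1
  sp <- bead_phantom_spec(disc_radius = 60, boundary_roughness = 0,
                          network_density = 0, texture_contrast = 0,
                          seed = 2)
  ph <- simulate_bead_image(sp)
  expect_equal(sum(ph$disc_mask), pi * 60^2, tolerance = 0.02)
  expect_gte(shape_descriptors(ph$disc_mask)$circularity, 0.95)
  expect_equal(sum(ph$network_mask), 0)
  # uniform interior
  expect_equal(length(unique(ph$image[ph$disc_mask])), 1L)

  # network present and confined to the disc
  ph2 <- simulate_bead_image(bead_phantom_spec(seed = 5))
  expect_gt(sum(ph2$network_mask), 0)
  expect_true(all(ph2$disc_mask[ph2$network_mask]))
  expect_true(all(ph2$image >= 0 & ph2$image <= 255))

  # disc must fit
  expect_error(bead_phantom_spec(image_size = 100, disc_radius = 60),
               "fit inside")
})

test_that("release CSV round-trips through write/read", {
  tr <- kinetic_truth("higuchi", c(k = 0.05), noise_sd = 0.01, seed = 4)
  pair <- simulate_digestion_pair(5e7, tr, seed = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_release_csv(pair$curve, path)
  back <- read_release_csv(path)
  expect_equal(back$fraction_released, pair$curve$fraction_released,
               tolerance = 1e-12)
  expect_equal(back$cfu_medium_per_ml, pair$curve$cfu_medium_per_ml,
               tolerance = 1e-12)
  expect_equal(attr(back, "m_infinity"), 5e7)
  expect_identical(back$phase, pair$curve$phase)
})

test_that("gray images round-trip through TIFF and PNG", {
  ph <- simulate_bead_image(bead_phantom_spec(image_size = 64,
                                              disc_radius = 20, seed = 9))
  for (ext in c(".tiff", ".png")) {
    path <- withr::local_tempfile(fileext = ext)
    write_gray_image(ph$image, path)
    back <- read_gray_image(path)
    expect_equal(back, ph$image, ignore_attr = TRUE)
  }
})
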