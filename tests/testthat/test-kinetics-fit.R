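noiseless_curve <- function(model_id, params) {
  simulate_release_curve(kinetic_truth(model_id, params, noise_sd = 0))
}

test_that("r_squared matches hand arithmetic and its contracts", {
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(r_squared(c(1, 2, 3), rep(2, 3)), 0)
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 4)), 0.5) # 1 - 1/2
  expect_error(r_squared(c(1, 1), c(1, 2)), "zero total variance")
  expect_error(r_squared(1:3, 1:4), "equal length")
})

test_that("zero-order fit recovers exact and degenerate inputs honestly", {
  cv <- noiseless_curve("zero_order", c(k = 0.004))
  fit <- fit_zero_order(cv)
  expect_equal(fit$params$k, 0.004, tolerance = 1e-12)
  expect_equal(fit$r2, 1, tolerance = 1e-12)

  # constant fraction: best k minimizes SSE, R^2 reported honestly (<= 0)
  flat <- release_curve(c(0, 10, 50, 100), rep(0.5, 4))
  ffit <- fit_zero_order(flat)
  t <- flat$time_min
  expect_equal(ffit$params$k, sum(t * 0.5) / sum(t^2), tolerance = 1e-12)
  expect_lte(ffit$r2, 0)

  expect_error(fit_zero_order(cv, window = 1L), "at least 2")
})

test_that("zero-order estimate is unbiased under additive noise", {
  ks <- vapply(1:200, function(s) {
    tr <- kinetic_truth("zero_order", c(k = 0.004), noise_sd = 0.01,
                        seed = s)
    fit_zero_order(simulate_release_curve(tr))$params$k
  }, numeric(1))
  expect_lt(abs(mean(ks) - 0.004), 0.0005)
})

test_that("Higuchi fit respects its fraction window", {
  cv <- noiseless_curve("higuchi", c(k = 0.05))
  fit <- fit_higuchi(cv)
  expect_equal(fit$params$k, 0.05, tolerance = 1e-12)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  # the recorded window only holds in-range fractions
  expect_true(all(cv$fraction_released[fit$window] > 0.1 &
                  cv$fraction_released[fit$window] < 0.6))

  # all fractions above 0.6: explicit insufficient-window error
  hi <- release_curve(c(0, 10, 50, 100), c(0.7, 0.8, 0.9, 0.95))
  expect_error(fit_higuchi(hi), "insufficient window.*0.1.*0.6")

  # nesting: two-term data with k2 = 0, m = 0.5 is pure sqrt(t)
  cv2 <- noiseless_curve("peppas_sahlin", list(k1 = 0.05, k2 = 0, m = 0.5))
  expect_equal(fit_higuchi(cv2)$params$k, 0.05, tolerance = 1e-9)
})

test_that("Korsmeyer-Peppas fit recovers published-style parameters", {
  cv <- noiseless_curve("korsmeyer_peppas", c(k = 0.0757, n = 0.4060))
  for (method in c("log_linear", "nonlinear")) {
    fit <- fit_korsmeyer_peppas(cv, method = method)
    expect_equal(fit$params$n, 0.4060, tolerance = 1e-6)
    expect_equal(fit$params$k, 0.0757, tolerance = 1e-6)
    expect_equal(fit$r2, 1, tolerance = 1e-9)
  }

  # n = 1 reduces to zero order
  cv1 <- noiseless_curve("korsmeyer_peppas", c(k = 0.003, n = 1))
  fit1 <- fit_korsmeyer_peppas(cv1)
  expect_equal(fit1$params$n, 1, tolerance = 1e-6)
  expect_equal(fit1$params$k,
               fit_zero_order(cv1)$params$k, tolerance = 1e-6)

  expect_error(
    fit_korsmeyer_peppas(release_curve(c(0, 1, 2), c(0, 0, 0.1))),
    "at least 3")
})

test_that("Peppas-Sahlin closed-form solve is exact, free-m close", {
  cv <- noiseless_curve("peppas_sahlin",
                        list(k1 = 0.01, k2 = 0.002, m = 0.43))
  fit <- fit_peppas_sahlin(cv, m = 0.43)
  expect_equal(fit$params$k1, 0.01, tolerance = 1e-9)
  expect_equal(fit$params$k2, 0.002, tolerance = 1e-9)
  expect_equal(fit$r2, 1, tolerance = 1e-12)

  # negative relaxation coefficient: signs recovered exactly
  cvn <- noiseless_curve("peppas_sahlin",
                         list(k1 = 5.726962e-2, k2 = -1.431741e-3,
                              m = 0.43))
  fitn <- fit_peppas_sahlin(cvn, m = 0.43)
  expect_gt(fitn$params$k1, 0)
  expect_lt(fitn$params$k2, 0)
  expect_equal(fitn$params$k1, 5.726962e-2, tolerance = 1e-9)

  # nesting: pure power law with n = m means k2 = 0
  cvk <- noiseless_curve("korsmeyer_peppas", c(k = 0.05, n = 0.43))
  fitk <- fit_peppas_sahlin(cvk, m = 0.43)
  expect_equal(fitk$params$k2, 0, tolerance = 1e-10)
  expect_equal(fitk$params$k1, 0.05, tolerance = 1e-9)

  # free-m mode profiles the exponent
  fitf <- fit_peppas_sahlin(cv, m = "free")
  expect_equal(fitf$params$m, 0.43, tolerance = 1e-3)
  expect_equal(fitf$params$k1, 0.01, tolerance = 1e-3)

  # too few points
  expect_error(fit_peppas_sahlin(release_curve(c(0, 1, 2),
                                               c(0, 0.1, 0.2))),
               "at least 4")
})

test_that("round-trip: every model refits its own noiseless curve to 1e-6", {
  cases <- list(
    list("zero_order", c(k = 0.0036)),
    list("higuchi", c(k = 0.055)),
    list("korsmeyer_peppas", c(k = 0.0757, n = 0.4060)),
    list("peppas_sahlin", list(k1 = 0.0573, k2 = -0.00143, m = 0.43)))
  for (cs in cases) {
    cv <- noiseless_curve(cs[[1]], cs[[2]])
    fit <- switch(cs[[1]],
                  zero_order = fit_zero_order(cv),
                  higuchi = fit_higuchi(cv),
                  korsmeyer_peppas = fit_korsmeyer_peppas(cv),
                  peppas_sahlin = fit_peppas_sahlin(cv, m = 0.43))
    truth <- as.list(cs[[2]])
    for (p in setdiff(names(truth), "m")) {
      expect_equal(fit$params[[p]], truth[[p]],
                   tolerance = 1e-6 * max(1, abs(truth[[p]])))
    }
    expect_equal(fit$r2, 1, tolerance = 1e-9)
  }
})

test_that("Korsmeyer-Peppas at n = 0.5 coincides with Higuchi on its window", {
  cv <- noiseless_curve("higuchi", c(k = 0.05))
  hig <- fit_higuchi(cv)
  kp <- fit_korsmeyer_peppas(cv, window = hig$window)
  expect_equal(kp$params$n, 0.5, tolerance = 1e-9)
  expect_equal(kp$params$k, hig$params$k, tolerance = 1e-9)
})

test_that("model selection maximizes R2 with parsimony tie-breaking", {
  fits <- list(a = structure(list(model_id = "zero_order", r2 = 0.50,
                                  n_free_params = 1L), class = "model_fit"),
               b = structure(list(model_id = "higuchi", r2 = 0.61,
                                  n_free_params = 1L), class = "model_fit"),
               c = structure(list(model_id = "peppas_sahlin", r2 = 0.89,
                                  n_free_params = 2L), class = "model_fit"))
  expect_equal(select_model(fits)$r2, 0.89)

  # exact tie: fewer parameters wins
  tie <- list(ps = structure(list(model_id = "peppas_sahlin", r2 = 0.9,
                                  n_free_params = 2L), class = "model_fit"),
              hig = structure(list(model_id = "higuchi", r2 = 0.9,
                                   n_free_params = 1L), class = "model_fit"))
  expect_equal(select_model(tie)$model_id, "higuchi")
  expect_error(select_model(list()), "empty")

  # generating model attains R2 = 1 and is selected, all four models
  gens <- list(zero_order = c(k = 0.0036),
               higuchi = c(k = 0.055),
               korsmeyer_peppas = c(k = 0.9 / 250^0.64, n = 0.64),
               peppas_sahlin = list(k1 = 0.0573, k2 = -0.00143, m = 0.43))
  for (g in names(gens)) {
    sel <- select_model(fit_release_models(noiseless_curve(g, gens[[g]])))
    expect_identical(sel$model_id, g)
    expect_equal(sel$r2, 1, tolerance = 1e-9)
  }

  # selected R2 >= every candidate's R2 (by construction, asserted)
  cv <- simulate_release_curve(
    kinetic_truth("korsmeyer_peppas", c(k = 0.02, n = 0.6),
                  noise_sd = 0.02, seed = 31))
  fits2 <- fit_release_models(cv)
  sel2 <- select_model(fits2)
  expect_true(all(sel2$r2 >= vapply(unclass(fits2),
                                    function(f) f$r2, numeric(1))))
})

test_that("noisy exponent recovery stays within its sampling precision", {
  errs <- vapply(1:100, function(s) {
    tr <- kinetic_truth("korsmeyer_peppas",
                        c(k = 0.9 / 250^0.64, n = 0.64),
                        noise_sd = 0.02, seed = 400 + s)
    fit_korsmeyer_peppas(simulate_release_curve(tr))$params$n - 0.64
  }, numeric(1))
  expect_lte(median(abs(errs)), 0.05)
})
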