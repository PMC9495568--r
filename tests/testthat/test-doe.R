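test_that("level coding is the exact involution on the design grid", {
  expect_equal(code_levels(3.75, 3.75), data.frame(a = 0, w = 0))
  expect_equal(code_levels(5, 2.5), data.frame(a = 1, w = -1))
  g <- factorial_design_grid()
  coded <- code_levels(g$agavin_pct, g$whey_pct)
  back <- decode_levels(coded$a, coded$w)
  expect_equal(back$agavin_pct, g$agavin_pct, tolerance = 1e-12)
  expect_equal(back$whey_pct, g$whey_pct, tolerance = 1e-12)
  expect_error(code_levels(6, 3), "design region")
  expect_error(decode_levels(1.5, 0), "within")
})

test_that("quadratic surface fit recovers noiseless coefficients exactly", {
  b <- c(b0 = 5.4, bA = 0.3, bW = 0.8, bAA = -0.5, bWW = -0.2,
         bAW = 0.15)
  dat <- simulate_factorial_experiment(
    factorial_truth(list(area = unname(b)), noise_sd = 0))
  m <- fit_quadratic_surface(dat, "area")
  expect_equal(m$coefficients, b, tolerance = 1e-9)
  expect_equal(m$r2, 1, tolerance = 1e-12)

  # constant response: b0 only
  datc <- simulate_factorial_experiment(
    factorial_truth(list(ee = c(96.77, 0, 0, 0, 0, 0)), noise_sd = 0))
  mc <- fit_quadratic_surface(datc, "ee")
  expect_equal(unname(mc$coefficients["b0"]), 96.77, tolerance = 1e-9)
  expect_equal(unname(mc$coefficients[-1]), rep(0, 5), tolerance = 1e-9)

  expect_error(fit_quadratic_surface(dat, "nope"), "no rows")
})

test_that("surface predictions honour training points and symmetry", {
  b <- c(2, 0.5, 0.5, -0.3, -0.3, 0.1) # symmetric in (a, w)
  dat <- simulate_factorial_experiment(
    factorial_truth(list(y = b), noise_sd = 0))
  m <- fit_quadratic_surface(dat, "y")
  # training values reproduced exactly
  expect_equal(predict_surface(m, dat$agavin_pct, dat$whey_pct),
               dat$value, tolerance = 1e-9)
  # swap symmetry
  expect_equal(predict_surface(m, 4.2, 2.9), predict_surface(m, 2.9, 4.2),
               tolerance = 1e-9)
  expect_error(predict_surface(m, 6, 3), "outside the design region")
  expect_silent(predict_surface(m, 6, 3, allow_extrapolation = TRUE))

  # whey-dominant linear surface peaks on the whey-rich edge
  bw <- c(2, 0.1, 1.5, 0, 0, 0)
  mw <- fit_quadratic_surface(simulate_factorial_experiment(
    factorial_truth(list(area = bw), noise_sd = 0)), "area")
  gseq <- seq(2.5, 5, length.out = 41)
  grid <- expand.grid(A = gseq, W = gseq)
  top <- grid[which.max(predict_surface(mw, grid$A, grid$W)), ]
  expect_equal(top$W, 5)
})

test_that("surface coefficients are unbiased under replicate noise", {
  b <- c(5, 0.4, -0.6, -0.8, 0.3, 0.2)
  est <- matrix(0, 100, 6)
  for (s in 1:100) {
    dat <- simulate_factorial_experiment(
      factorial_truth(list(y = b), noise_sd = 0.5, seed = s))
    est[s, ] <- fit_quadratic_surface(dat, "y")$coefficients
  }
  se <- apply(est, 2, sd) / sqrt(100)
  expect_true(all(abs(colMeans(est) - b) <= 3 * se + 1e-9))
})

test_that("desirability transforms implement the one-sided ramps", {
  gmax <- desirability_goal("y", "maximize", 0, 10)
  gmin <- desirability_goal("y", "minimize", 0, 10)
  expect_equal(desirability(10, gmax), 1)
  expect_equal(desirability(10, gmin), 0)
  expect_equal(desirability(5, gmax), 0.5)
  expect_equal(desirability(5, gmin), 0.5)
  expect_equal(desirability(-3, gmax), 0)
  expect_equal(desirability(15, gmax), 1)
  gw <- desirability_goal("y", "maximize", 0, 10, weight = 2)
  expect_equal(desirability(5, gw), 0.25)
  expect_error(desirability_goal("y", "maximize", 5, 5), "lower")
})

test_that("composite optimization agrees with the exhaustive grid oracle", {
  b <- c(5.4, 0.3, 0.8, -0.5, -0.2, 0.15)
  dat <- simulate_factorial_experiment(
    factorial_truth(list(area = b), noise_sd = 0))
  m <- fit_quadratic_surface(dat, "area")
  goal <- goal_from_surface(m, "maximize")
  res <- optimize_composite(list(m), list(goal))

  gseq <- seq(2.5, 5, length.out = 201)
  grid <- expand.grid(A = gseq, W = gseq)
  d <- desirability(predict_surface(m, grid$A, grid$W), goal)
  best <- which.max(d)
  step <- gseq[2] - gseq[1]
  expect_lte(abs(res$optimal["agavin_pct"] - grid$A[best]), step)
  expect_lte(abs(res$optimal["whey_pct"] - grid$W[best]), step)
  expect_gte(res$composite + 1e-12, max(d))

  # conflicting mirrored goals: optimum at the symmetry point
  b1 <- c(2, 1, 0, 0, 0, 0)
  b2 <- c(2, -1, 0, 0, 0, 0)
  dat2 <- rbind(
    simulate_factorial_experiment(factorial_truth(list(up = b1),
                                                  noise_sd = 0)),
    simulate_factorial_experiment(factorial_truth(list(dn = b2),
                                                  noise_sd = 0)))
  m1 <- fit_quadratic_surface(dat2, "up")
  m2 <- fit_quadratic_surface(dat2, "dn")
  g1 <- desirability_goal("up", "maximize", 1, 3)
  g2 <- desirability_goal("dn", "maximize", 1, 3)
  res2 <- optimize_composite(list(m1, m2), list(g1, g2))
  expect_equal(unname(res2$optimal["agavin_pct"]), 3.75, tolerance = 0.02)

  # geometric-mean zero property: one zero desirability kills the product
  gz <- desirability_goal("up", "maximize", 10, 20) # unreachable
  resz <- optimize_composite(list(m1), list(gz))
  expect_true(resz$all_zero)
  expect_equal(resz$composite, 0)
})

test_that("the standard morphometric goal set optimizes four surfaces", {
  # maximize area/circularity/solidity, minimize perimeter
  truth <- factorial_truth(list(
    area = c(5.4, 0.3, 0.9, -0.4, -0.1, 0.1),
    perimeter = c(9.1, 0.2, 0.9, 0.1, 0.2, 0),
    circularity = c(0.78, 0.05, 0.03, -0.04, -0.05, 0.01),
    solidity = c(0.98, 0.01, 0.002, -0.008, -0.006, 0.001)),
    noise_sd = 0)
  dat <- simulate_factorial_experiment(truth)
  models <- lapply(names(truth$coefficients),
                   function(r) fit_quadratic_surface(dat, r))
  goals <- list(
    goal_from_surface(models[[1]], "maximize"),
    goal_from_surface(models[[2]], "minimize"),
    goal_from_surface(models[[3]], "maximize"),
    goal_from_surface(models[[4]], "maximize"))
  res <- optimize_composite(models, goals)
  expect_true(res$composite > 0 && res$composite <= 1)
  expect_true(all(res$optimal >= 2.5 & res$optimal <= 5))
  # composite equals the weighted geometric mean of the parts
  ds <- vapply(res$per_response, function(x) x[["desirability"]],
               numeric(1))
  expect_equal(res$composite, prod(ds)^(1 / length(ds)),
               tolerance = 1e-6)
})

test_that("one-way ANOVA with Tukey letters separates what it should", {
  set.seed(5)
  # identical groups: one shared letter, nothing significant
  v0 <- rnorm(12)
  a0 <- anova_tukey(v0, rep(letters[1:4], each = 3))
  expect_true(all(a0$letters == a0$letters[1]))

  # two groups 10 pooled sds apart, n = 3: significant
  v1 <- c(rnorm(3, 0, 1), rnorm(3, 10, 1))
  a1 <- anova_tukey(v1, rep(c("lo", "hi"), each = 3))
  expect_lt(a1$p_value, 0.05)
  expect_false(a1$letters["hi"] == a1$letters["lo"])

  # means 0/0/5: exactly the two pairs involving the third significant
  v2 <- c(rnorm(3, 0, 0.5), rnorm(3, 0, 0.5), rnorm(3, 5, 0.5))
  a2 <- anova_tukey(v2, rep(c("g1", "g2", "g3"), each = 3))
  sig <- a2$tukey[, "p adj"] < 0.05
  expect_identical(unname(sig[c("g2-g1", "g3-g1", "g3-g2")]),
                   c(FALSE, TRUE, TRUE))
  expect_identical(unname(a2$letters["g1"]), unname(a2$letters["g2"]))
  expect_false(a2$letters["g3"] == a2$letters["g1"])
  # highest mean carries letter "a"
  expect_identical(unname(a2$letters[names(a2$means)[1]]), "a")

  expect_error(anova_tukey(1:4, c("a", "a", "a", "b")), "at least 2")
  expect_error(anova_tukey(1:6, rep(c("a", "b"), each = 3), alpha = 1.2),
               "alpha|<=")
})
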