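test_that("sphere-contact force evaluates the closed form", {
  # E = 5.3 kPa, R = 65 nm, delta = 50 nm, nu = 0.5:
  # (4/3)*(5.3e-3/0.75)*sqrt(65)*50^1.5 pN
  expect_equal(hertz_force(5.3, 65, 50), 26.8575, tolerance = 1e-4)
  expect_equal(hertz_force(5.3, 65, 0), 0)
  expect_equal(hertz_force(10.6, 65, 50), 2 * hertz_force(5.3, 65, 50))
  expect_error(hertz_force(5.3, 65, -1), "delta")
  expect_error(hertz_force(-1, 65, 1), "E")
  expect_error(hertz_force(5, 65, 1, nu = 0.7), "nu")
})

test_that("the finite-thickness model reduces to the half-space model as the layer thickens", {
  R <- 65; d <- 50; E <- 10.7
  # the leading correction term is 0.884*alpha, so the relative deviation at
  # alpha is ~0.884*alpha: below 1e-10 once alpha <= 1e-10
  h <- sqrt(R * d) / 1e-12
  expect_lt(abs(bottom_effect_force(E, R, d, h) /
                hertz_force(E, R, d, 0.5) - 1), 1e-10)
  h6 <- sqrt(R * d) / 1e-6
  expect_equal(bottom_effect_force(E, R, d, h6) / hertz_force(E, R, d, 0.5),
               1 + 0.884e-6, tolerance = 1e-10)
})

test_that("the thin-layer correction factor matches the printed polynomial", {
  R <- 65; d <- 50; h <- 200
  a <- sqrt(R * d) / h
  fac <- 1 + 0.884 * a + 0.781 * a^2 + 0.386 * a^3 + 0.0048 * a^4
  expect_equal(bottom_effect_force(3, R, d, h) / hertz_force(3, R, d, 0.5),
               fac, tolerance = 1e-12)
  expect_equal(fac, 1.3244064, tolerance = 1e-7)
})

test_that("the corrected force grows as the layer thins", {
  f <- vapply(c(400, 200, 100, 50), function(h)
    bottom_effect_force(5, 65, 50, h), numeric(1))
  expect_true(all(diff(f) > 0))
  expect_error(bottom_effect_force(5, 65, 50, 0), "h must be > 0")
})

test_that("the Hertz slope fit recovers a noise-free modulus essentially exactly", {
  ic <- make_indentation(function(d) hertz_force(10.7, 65, d), dmax = 200)
  fit <- hertz_slope_fit(ic, c(0, 200), R = 65)
  expect_equal(fit$E, 10.7, tolerance = 1e-3)   # < 0.1 %
  expect_true(fit$converged)
  expect_lt(fit$rms, 1e-8)
})

test_that("the Hertz slope fit is exactly scale-equivariant", {
  set.seed(21)
  for (i in 1:5) {
    E <- runif(1, 3, 40); cfac <- runif(1, 0.2, 5)
    ic <- make_indentation(function(d) hertz_force(E, 65, d) + rnorm(length(d), sd = 10))
    ic2 <- ic; ic2$force <- cfac * ic$force
    f1 <- hertz_slope_fit(ic, c(0, 200), 65)
    f2 <- hertz_slope_fit(ic2, c(0, 200), 65)
    expect_equal(f2$E, cfac * f1$E, tolerance = 1e-10)
  }
})

test_that("noisy single-curve moduli are recovered within 10% (median)", {
  set.seed(31)
  errs <- vapply(1:100, function(i) {
    ic <- make_indentation(function(d)
      hertz_force(10.7, 65, d) + rnorm(length(d), sd = 15), dmax = 200)
    hertz_slope_fit(ic, c(0, 200), 65)$E / 10.7 - 1
  }, numeric(1))
  expect_lt(median(abs(errs)), 0.10)
})

test_that("sparse windows and nonpositive slopes are reported, not invented", {
  ic <- make_indentation(function(d) hertz_force(5, 65, d), dmax = 10, n = 12)
  expect_error(hertz_slope_fit(ic, c(50, 200), 65), "fewer than 8")
  set.seed(4)
  icn <- make_indentation(function(d) -0.5 * d + rnorm(length(d), sd = 1),
                          dmax = 200)
  fit <- hertz_slope_fit(icn, c(0, 200), 65)
  expect_false(fit$converged)
  expect_true(is.na(fit$E))
})

test_that("depth segmentation separates membrane and cortex moduli (noise-free)", {
  sc <- build_scene(2, 2, coverage = 0, e_pm_out = 5.3, e_cortex = 37.5,
                    noise_sd = 0, drift = c(0, 0, 0), seed = 1)
  fc <- simulate_curve(pixel_truth(sc, 1, 1), default_acq, seed = 2)
  fit <- fit_curve(fc)
  expect_equal(fit$mechanics$E_pm, 5.3, tolerance = 0.05)
  expect_equal(fit$mechanics$E_cortex, 37.5, tolerance = 0.05)
  # independent per-window fits agree on the same data
  ic <- to_indentation(correct_baseline(fc), 200)
  win <- segmented_moduli(ic, 65, 0.5, fv_config(segment_method = "window"))
  expect_equal(win$E_pm, 5.3, tolerance = 0.05)
  expect_equal(win$E_cortex, 37.5, tolerance = 0.05)
})

test_that("a homogeneous half-space yields equal moduli in both windows", {
  ic <- make_indentation(function(d) hertz_force(10, 65, d), dmax = 220,
                         n = 512)
  for (method in c("joint", "window")) {
    fit <- segmented_moduli(ic, 65, 0.5, fv_config(segment_method = method))
    expect_equal(fit$E_pm, fit$E_cortex, tolerance = 0.02)
  }
})

test_that("the cortex modulus is absent when the curve stays shallow", {
  ic <- make_indentation(function(d) hertz_force(10, 65, d), dmax = 40,
                         n = 128)
  fit <- segmented_moduli(ic, 65)
  expect_true(is.na(fit$E_cortex))
  expect_equal(fit$E_pm, 10, tolerance = 0.01)
})

test_that("the bottom-effect fit inverts its own forward model", {
  ic <- make_indentation(function(d) bottom_effect_force(10.7, 65, d, h = 50),
                         dmax = 50, n = 128)
  fit <- bottom_effect_fit(ic, c(0, 50), 65, h = 50)
  expect_equal(fit$E, 10.7, tolerance = 1e-10)
  # ignoring the substrate on a thin layer overestimates the modulus
  plain <- hertz_slope_fit(ic, c(0, 50), 65)
  expect_gt(plain$E, 10.7)
  # zero-force data cannot converge
  ic0 <- make_indentation(function(d) numeric(length(d)), dmax = 50, n = 64)
  f0 <- bottom_effect_fit(ic0, c(0, 50), 65, h = 50)
  expect_false(f0$converged)
  expect_true(is.na(f0$E))
})

test_that("pooled group fits recover two-layer moduli from a clean map", {
  sc <- build_scene(3, 3, coverage = 0, e_pm_out = 5.3, e_cortex = 37.5,
                    noise_sd = 0, drift = c(0, 0, 0), seed = 2)
  m <- simulate_map(sc, default_acq, seed = 2)
  pf <- pooled_moduli(m, sweeps = 4)
  expect_equal(pf$E_pm, 5.3, tolerance = 0.02)
  expect_equal(pf$E_cortex, 37.5, tolerance = 0.02)
  expect_equal(unname(pf$z0), rep(200, 9), tolerance = 1e-2)
})
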