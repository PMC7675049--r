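test_that("quadratic baseline drift is removed from the off-contact area", {
  set.seed(1)
  fc <- make_hertz_curve(E = 10, z0 = 200, depth = 200, n = 512, noise = 5,
                         seed = 1, drift = c(2, 0.01, 2e-5))
  cc <- correct_baseline(fc, 0.3)
  for (seg in c("approach", "retract")) {
    s <- cc[[seg]]
    off <- s$z < 0.3 * max(s$z)
    expect_lt(abs(mean(s$force[off])), 0.5)
  }
})

test_that("an already-flat curve is unchanged within fit noise", {
  fc <- make_hertz_curve(E = 10, z0 = 200, n = 512, noise = 0)
  cc <- correct_baseline(fc, 0.3)
  expect_lt(max(abs(cc$approach$force - fc$approach$force)), 1e-8)
})

test_that("pure quadratic drift with no contact is fully removed under full extrapolation", {
  z <- seq(0, 400, length.out = 256)
  f <- 2 + 0.01 * z + 2e-5 * z^2
  fc <- force_curve(cbind(z, f), cbind(rev(z), rev(f)))
  cc <- correct_baseline(fc, 0.3, extrapolate = "full")
  expect_lt(max(abs(cc$retract$force)), 1e-9)
  expect_lt(max(abs(cc$approach$force)), 1e-9)
})

test_that("baseline correction demands enough off-contact samples", {
  z <- seq(0, 100, length.out = 40)
  fc <- force_curve(cbind(z, 0), cbind(rev(z), 0))
  expect_error(correct_baseline(fc, 0.2), "16 off-contact")
})

test_that("noise estimate matches the injected white-noise level", {
  # ~1000 off-contact samples at fraction 0.3
  set.seed(42)
  n <- 3334
  z <- seq(0, 400, length.out = n)
  f <- rnorm(n, sd = 15)
  fc <- force_curve(cbind(z, f), cbind(rev(z), rev(rnorm(n, sd = 15))))
  est <- estimate_noise(fc, 0.3)
  expect_equal(est$sigma, 15, tolerance = 1 / 15)  # +-1 pN
  expect_equal(est$n_samples, 1000L)
})

test_that("a zero-noise curve has zero estimated noise", {
  fc <- make_hertz_curve(noise = 0, n = 256)
  expect_equal(estimate_noise(fc)$sigma, 0, tolerance = 1e-10)
})

test_that("a linear tilt is absorbed by the straight-line noise fit", {
  set.seed(7)
  n <- 3334
  z <- seq(0, 400, length.out = n)
  f <- 0.05 * z + rnorm(n, sd = 15)
  fc <- force_curve(cbind(z, f), cbind(rev(z), rev(0.05 * z + rnorm(n, sd = 15))))
  expect_equal(estimate_noise(fc, 0.3)$sigma, 15, tolerance = 1.5 / 15)
})

test_that("the noise estimator is unbiased on synthetic white noise", {
  set.seed(99)
  n <- 3334
  z <- seq(0, 400, length.out = n)
  sig <- vapply(1:100, function(i) {
    fr <- rnorm(n, sd = 15)
    fc <- force_curve(cbind(z, 0), cbind(rev(z), fr))
    estimate_noise(fc, 0.3)$sigma
  }, numeric(1))
  expect_lt(abs(mean(sig) / 15 - 1), 0.02)
})

test_that("the contact point of a noise-free curve is recovered to a sample", {
  fc <- make_hertz_curve(E = 10, z0 = 100, depth = 150, n = 512, noise = 0)
  cp <- locate_contact_point(fc)
  dz <- diff(fc$approach$z[1:2])
  expect_false(cp$no_contact)
  expect_lt(abs(cp$z0 - 100), dz)
})

test_that("an all-noise curve is flagged no-contact", {
  set.seed(3)
  z <- seq(0, 400, length.out = 256)
  fc <- force_curve(cbind(z, rnorm(256, sd = 15)),
                    cbind(rev(z), rnorm(256, sd = 15)))
  cp <- locate_contact_point(fc)
  expect_true(cp$no_contact)
  expect_true(is.na(cp$z0))
  fit <- fit_curve(fc)
  expect_true(fit$no_contact)
  expect_null(fit$mechanics)
})

test_that("contact recovery stays within 5 nm for most noisy curves", {
  # healthy-cell layer contrast, imaging force 500 pN, 15 pN noise
  acq <- acquisition_params(setpoint_force = 500)
  sc <- build_scene(15, 14, coverage = 0, e_pm_out = 5.3, e_cortex = 37.5,
                    noise_sd = 15, seed = 77)
  m <- simulate_map(sc, acq, seed = 77)
  errs <- vapply(1:200, function(i) {
    r <- (i - 1) %/% 14 + 1; c <- (i - 1) %% 14 + 1
    fit_curve(map_curve(m, r, c))$z0 - 200
  }, numeric(1))
  expect_gte(mean(abs(errs) <= 5), 0.95)
})

test_that("contact-point error shrinks as noise shrinks", {
  acq <- acquisition_params()
  med_err <- vapply(c(0, 5, 15), function(s) {
    sc <- build_scene(4, 5, coverage = 0, e_pm_out = 5.3, e_cortex = 37.5,
                      noise_sd = s, seed = 55)
    m <- simulate_map(sc, acq, seed = 55)
    median(vapply(1:20, function(i) {
      r <- (i - 1) %/% 5 + 1; c <- (i - 1) %% 5 + 1
      abs(fit_curve(map_curve(m, r, c))$z0 - 200)
    }, numeric(1)))
  }, numeric(1))
  expect_lte(med_err[1], med_err[3] + 0.5)
  expect_lte(med_err[2], med_err[3] + 0.5)
})

test_that("indentation applies the deflection correction arithmetic", {
  # 500 pN at 55 nm past contact with k = 0.1 N/m -> 5 nm deflection
  z <- seq(0, 100, length.out = 64)
  f <- numeric(64)
  f[64] <- 500
  fc <- force_curve(cbind(z, f), cbind(rev(z), rev(f)))
  ic <- to_indentation(fc, z0 = z[64] - 55, k = 0.1)
  expect_equal(ic$delta[ic$force == 500], 50, tolerance = 1e-10)
  # zero force: indentation equals piezo travel past contact
  ic0 <- to_indentation(force_curve(cbind(z, 0), cbind(rev(z), 0)), z0 = 40,
                        k = 0.1)
  expect_equal(max(ic0$delta), 60, tolerance = 1e-10)
  # stiff limit: deflection vanishes
  ics <- to_indentation(fc, z0 = z[64] - 55, k = 10)
  expect_equal(ics$delta[ics$force == 500], 55 - 500 / 10000,
               tolerance = 1e-10)
  expect_error(to_indentation(fc, z0 = 40, k = 0), "k must be > 0")
})

test_that("indentation is clipped at zero and nondecreasing", {
  set.seed(5)
  fc <- make_hertz_curve(E = 8, z0 = 150, noise = 10, seed = 5, n = 512)
  ic <- to_indentation(fc, 150)
  expect_true(all(ic$delta >= 0))
  expect_true(all(diff(ic$delta) >= 0))
})
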