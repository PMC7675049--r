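test_that("the WLC interpolation formula evaluates its closed form", {
  expect_equal(wlc_force(0, 0.38, 30), 0)
  # half extension: F = 1.25 kBT/Lp
  kBT <- 1.380649e-2 * 310
  expect_equal(wlc_force(15, 0.38, 30), 1.25 * kBT / 0.38, tolerance = 1e-10)
  expect_equal(wlc_force(15, 0.38, 30), 14.079, tolerance = 1e-4)
  # diverges monotonically approaching the contour length
  f <- wlc_force(seq(25, 29.9, by = 0.1), 0.38, 30)
  expect_true(all(diff(f) > 0))
  expect_error(wlc_force(30, 0.38, 30), "0 <= x < Lc")
  expect_error(wlc_force(1, 2, 1), "Lp < Lc")
})

test_that("a single injected tether rupture yields one well-placed candidate", {
  sc <- build_scene(2, 2, coverage = 0.95, p_bind = 1, rupture_min = 80,
                    lc_range = c(30, 30), seed = 2)
  tr <- pixel_truth(sc, 1, 1)
  n1 <- 0; derr <- ferr <- c()
  for (s in 1:30) {
    fc <- simulate_curve(tr, default_acq, seed = 700 + s)
    tru <- attr(fc, "truth")$event
    fit <- fit_curve(fc)
    if (length(fit$events) == 1L) n1 <- n1 + 1
    if (length(fit$events)) {
      e <- fit$events[[1]]
      derr <- c(derr, e$rupture_distance - tru$x_rup)
      ferr <- c(ferr, e$rupture_force - tru$f_rup)
    }
  }
  expect_gte(n1, 27)                   # one candidate nearly always
  # distance errors inherit the per-curve contact-point uncertainty (a few nm)
  expect_lt(median(abs(derr)), 5)
  expect_lt(median(abs(ferr)), 20)     # force within ~1.3 sigma
})

test_that("flat noisy retractions almost never produce candidates", {
  sc <- build_scene(2, 2, coverage = 0, e_pm_out = 9, e_cortex = 15.9,
                    seed = 3)
  tr <- pixel_truth(sc, 1, 1)
  n_cand <- vapply(1:200, function(s) {
    length(fit_curve(simulate_curve(tr, default_acq, seed = 900 + s))$events)
  }, numeric(1))
  expect_gte(mean(n_cand == 0), 0.95)
})

test_that("multiple ruptures are returned in order of distance", {
  set.seed(12)
  n <- 512
  z <- seq(400, 0, length.out = n)  # retract, descending
  z0 <- 300
  s_sep <- pmax(z0 - z, 0)
  f <- numeric(n)
  f[s_sep > 0 & s_sep <= 8] <- -120 * (s_sep[s_sep > 0 & s_sep <= 8] / 8)^2
  f[s_sep > 9 & s_sep <= 20] <- -130 * ((s_sep[s_sep > 9 & s_sep <= 20] - 9) / 11)^2
  f <- f + rnorm(n, sd = 3)
  fc <- force_curve(cbind(rev(z), rev(numeric(n))), cbind(z, f))
  ev <- detect_ruptures(fc, list(sigma = 3), z0)
  expect_gte(length(ev), 2L)
  d <- vapply(ev, `[[`, numeric(1), "rupture_distance")
  expect_true(all(diff(d) > 0))
  expect_equal(d[1], 8, tolerance = 2)
  expect_equal(d[2], 20, tolerance = 2)
})

test_that("a WLC-shaped pull is validated and its contour length recovered", {
  set.seed(8)
  n <- 512
  z <- seq(400, 0, length.out = n)
  z0 <- 300
  kp <- 100
  # parametric tether: z = z0 - x - F(x)/k up to rupture at 130 pN
  x_rup <- uniroot(function(x) wlc_force(x, 0.38, 30) - 130, c(1, 29.99))$root
  xs <- seq(0, x_rup, length.out = 512)
  fs <- c(0, wlc_force(xs[-1], 0.38, 30))
  zs <- z0 - xs - fs / kp
  f <- numeric(n)
  sel <- z < z0 & z >= min(zs)
  f[sel] <- -approx(rev(zs), rev(fs), xout = z[sel])$y
  f <- f + rnorm(n, sd = 5)
  fc <- force_curve(cbind(rev(z), rev(rnorm(n, sd = 5))), cbind(z, f))
  noise <- list(sigma = 5)
  ev <- detect_ruptures(fc, noise, z0)
  expect_length(ev, 1L)
  v <- validate_wlc(fc, ev[[1]], noise, z0)
  expect_false(is.null(v$wlc))
  expect_equal(v$wlc$Lc, 30, tolerance = 0.10)
  # one sample of piezo travel hides ~30 pN of force rise on this tether, so
  # a single draw can sit a sample's worth below the break force
  expect_equal(v$rupture_force, 130, tolerance = 25 / 130)
})

test_that("a Hookean pull of equal depth fails the WLC residual criterion", {
  set.seed(9)
  n <- 512
  z <- seq(400, 0, length.out = n)
  z0 <- 300
  s_sep <- pmax(z0 - z, 0)
  f <- numeric(n)
  f[s_sep > 0 & s_sep <= 13] <- -130 * s_sep[s_sep > 0 & s_sep <= 13] / 13
  f <- f + rnorm(n, sd = 5)
  fc <- force_curve(cbind(rev(z), rev(rnorm(n, sd = 5))), cbind(z, f))
  noise <- list(sigma = 5)
  ev <- detect_ruptures(fc, noise, z0)
  expect_gte(length(ev), 1L)
  v <- validate_wlc(fc, ev[[1]], noise, z0)
  expect_null(v$wlc)
  expect_equal(v$wlc_reject, "rms")
})

test_that("segments too short to constrain the WLC are rejected with a reason", {
  set.seed(10)
  n <- 512
  z <- seq(400, 0, length.out = n)
  z0 <- 300
  s_sep <- pmax(z0 - z, 0)
  f <- numeric(n)
  f[s_sep > 0 & s_sep <= 3] <- -120 * (s_sep[s_sep > 0 & s_sep <= 3] / 3)^2
  f <- f + rnorm(n, sd = 5)
  fc <- force_curve(cbind(rev(z), rev(rnorm(n, sd = 5))), cbind(z, f))
  noise <- list(sigma = 5)
  ev <- detect_ruptures(fc, noise, z0)
  expect_gte(length(ev), 1L)
  v <- validate_wlc(fc, ev[[1]], noise, z0)
  expect_null(v$wlc)
  expect_equal(v$wlc_reject, "too_short")
})

test_that("the in-package WLC fit agrees with an independent nonlinear fitter", {
  set.seed(11)
  kBT <- 1.380649e-2 * 310
  x <- seq(0.5, 26, by = 0.5)
  y <- wlc_force(x, 0.38, 30) + rnorm(length(x), sd = 2)
  fit <- fvmech:::cpp_wlc_fit(x, y, kBT, 0.38, 30, 0.05, 2, 3, 120, 0, 0)
  ref <- minpack.lm::nlsLM(
    y ~ (kBT / lp) * (0.25 * (1 - x / lc)^-2 - 0.25 + x / lc),
    start = list(lp = 0.38, lc = 30),
    lower = c(0.05, 3), upper = c(2, 120))
  expect_equal(fit$lp, unname(coef(ref)["lp"]), tolerance = 1e-3)
  expect_equal(fit$lc, unname(coef(ref)["lc"]), tolerance = 1e-3)
  expect_equal(fit$rms, sqrt(mean(residuals(ref)^2)), tolerance = 1e-4)
})

test_that("specificity follows the printed force and distance gates", {
  mk <- function(force, dist, wlc = TRUE) {
    e <- structure(list(rupture_force = force, rupture_distance = dist,
                        index = 1L, wlc = if (wlc) list(Lc = 30) else NULL,
                        wlc_reject = NULL, specific = NA),
                   class = "adhesion_event")
    classify_specific(e)$specific
  }
  expect_true(mk(141, 12))          # printed mean force, clear of both gates
  expect_false(mk(60, 12))          # below the 80 pN gate
  expect_false(mk(141, 3))          # below the 5 nm gate
  expect_false(mk(141, 12, wlc = FALSE))  # no validated tether model
  expect_false(mk(80, 12))          # strict inequality at the gate
})

test_that("specificity is monotone in force and distance", {
  set.seed(13)
  for (i in 1:50) {
    f <- runif(1, 0, 200); d <- runif(1, 0, 20)
    e <- structure(list(rupture_force = f, rupture_distance = d, index = 1L,
                        wlc = list(Lc = 30), wlc_reject = NULL, specific = NA),
                   class = "adhesion_event")
    s1 <- classify_specific(e)$specific
    e$rupture_force <- f + runif(1, 0, 100)
    e$rupture_distance <- d + runif(1, 0, 10)
    s2 <- classify_specific(e)$specific
    expect_false(s1 && !s2)
  }
})

test_that("pixels stratify into cholesterol, non-adhesive and indeterminate", {
  mk <- function(force, specific) {
    structure(list(rupture_force = force, rupture_distance = 10, index = 1L,
                   wlc = if (specific) list(Lc = 30) else NULL,
                   wlc_reject = NULL, specific = specific),
              class = "adhesion_event")
  }
  expect_equal(stratify_pixel(list(mk(129, TRUE))), "cholesterol")
  expect_equal(stratify_pixel(list()), "non_adhesive")
  expect_equal(stratify_pixel(list(mk(20, FALSE))), "non_adhesive")
  expect_equal(stratify_pixel(list(mk(60, FALSE))), "indeterminate")
  expect_equal(stratify_pixel(list(mk(95, TRUE))), "indeterminate")
})
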