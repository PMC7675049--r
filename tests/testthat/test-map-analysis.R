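test_that("map analysis assembles channels on the full grid", {
  m <- small_map(8, 8, seed = 21, coverage = 0.2)
  an <- analyze_map(m)
  for (ch in c("height", "E_pm", "E_cortex", "adhesion_force", "specific",
               "analyzed"))
    expect_equal(dim(an$channels[[ch]]), c(8L, 8L))
  expect_equal(dim(an$strata), c(8L, 8L))
  expect_equal(an$n_analyzed, sum(an$channels$analyzed))
})

test_that("pixels without contact are absent from all derived channels", {
  m <- small_map(3, 3, seed = 22, coverage = 0)
  # overwrite one pixel with an all-noise curve (no contact)
  set.seed(22)
  z <- seq(0, 400, length.out = 512)
  m$curves[[5]] <- force_curve(cbind(z, rnorm(512, sd = 15)),
                               cbind(rev(z), rnorm(512, sd = 15)),
                               row = 2, col = 2, acq = m$acq)
  an <- analyze_map(m)
  expect_false(an$channels$analyzed[2, 2])
  expect_true(is.na(an$channels$E_pm[2, 2]))
  expect_true(is.na(an$channels$height[2, 2]))
  expect_true(is.na(an$strata[2, 2]))
  expect_false(an$channels$specific[2, 2])
})

test_that("binding probability is the specific-pixel percentage of analysed pixels", {
  mask <- matrix(FALSE, 10, 10)
  mask[1:8] <- TRUE
  expect_equal(binding_probability(mask), 8)
  expect_equal(binding_probability(matrix(FALSE, 5, 5)), 0)
  expect_warning(bp <- binding_probability(mask, matrix(FALSE, 10, 10)),
                 "no analysed")
  expect_true(is.na(bp))
  # invariant: mask mean times 100, invariant to pixel order
  set.seed(30)
  m2 <- matrix(runif(144) < 0.3, 12, 12)
  expect_equal(binding_probability(m2), 100 * mean(m2))
  perm <- matrix(sample(m2), 12, 12)
  expect_equal(binding_probability(perm), binding_probability(m2))
})

test_that("domain connectivity semantics: diagonal blobs merge only under 8-connectivity", {
  mask <- matrix(FALSE, 5, 5)
  mask[cbind(c(1, 1, 2), c(1, 2, 2))] <- TRUE          # 3 pixels
  mask[cbind(c(3, 3, 4, 4), c(3, 4, 3, 4))] <- TRUE    # 4 pixels, diagonal touch
  d8 <- domain_sizes(mask, connectivity = 8)
  d4 <- domain_sizes(mask, connectivity = 4)
  expect_equal(sort(d8$size_px), 7)
  expect_equal(sort(d4$size_px), c(3, 4))
  expect_error(domain_sizes(mask, connectivity = 6), "4 or 8")
})

test_that("a single specific pixel is one domain of ~100x100 nm", {
  mask <- matrix(FALSE, 4, 4); mask[2, 3] <- TRUE
  d <- domain_sizes(mask, pixel_size = 100)
  expect_equal(d$size_px, 1L)
  expect_equal(d$area_nm2, 1e4)
})

test_that("labeling agrees with an independent implementation (4-connectivity)", {
  set.seed(41)
  for (i in 1:5) {
    mask <- matrix(runif(400) < 0.35, 20, 20)
    ours <- domain_sizes(mask, connectivity = 4)
    ref <- EBImage::bwlabel(mask * 1L)
    expect_equal(nrow(ours), max(ref))
    expect_equal(sort(ours$size_px), sort(as.integer(table(ref[ref > 0]))))
  }
})

test_that("domain sizes conserve the specific-pixel count", {
  set.seed(42)
  for (conn in c(4, 8)) {
    mask <- matrix(runif(625) < 0.25, 25, 25)
    d <- domain_sizes(mask, connectivity = conn)
    expect_equal(sum(d$size_px), sum(mask))
    labs <- attr(d, "labels")
    expect_equal(labs > 0, mask)
  }
})

test_that("noise-free simulated domains are recovered exactly", {
  sc <- build_scene(8, 8, coverage = 0.3, noise_sd = 0, drift = c(0, 0, 0),
                    p_bind = 1, rupture_min = 90, seed = 43)
  m <- simulate_map(sc, default_acq, seed = 43)
  an <- analyze_map(m)
  expect_equal(an$channels$specific, sc$domain_mask)
  expect_equal(sort(domain_sizes(an)$size_px),
               sort(domain_sizes(sc$domain_mask)$size_px))
})

test_that("binding probability tracks scene ground truth on generated maps", {
  m <- small_map(16, 16, seed = 44, coverage = 0.25)
  an <- analyze_map(m)
  truth <- scene_specific_truth(m)
  est <- binding_probability(an) / 100 * an$n_analyzed
  lohi <- qbinom(c(0.005, 0.995), an$n_analyzed, mean(truth))
  expect_gte(est, lohi[1])
  expect_lte(est, lohi[2])
})

test_that("stratified membrane elasticity separates the printed group means", {
  sc <- build_scene(10, 10, coverage = 0.35, e_pm_in = 13.1, e_pm_out = 9.0,
                    e_cortex = 15.9, rupture_min = 80, seed = 45)
  m <- simulate_map(sc, default_acq, seed = 45)
  inside <- pooled_moduli(m, pixels = sc$domain_mask, sweeps = 8)
  outside <- pooled_moduli(m, pixels = !sc$domain_mask, sweeps = 8)
  expect_equal(inside$E_pm, 13.1, tolerance = 0.10)
  expect_equal(outside$E_pm, 9.0, tolerance = 0.10)
  an <- analyze_map(m)
  st <- stratified_pm_elasticity(an)
  expect_false(st$skipped)
  expect_gt(mean(st$cholesterol), mean(st$non_adhesive))
})

test_that("a homogeneous membrane shows no stratum difference", {
  sc <- build_scene(10, 10, coverage = 0.4, e_pm_in = 9, e_pm_out = 9,
                    e_cortex = 15.9, rupture_min = 80, seed = 46)
  m <- simulate_map(sc, default_acq, seed = 46)
  st <- stratified_pm_elasticity(analyze_map(m))
  expect_false(st$skipped)
  se <- sqrt(var(st$cholesterol) / length(st$cholesterol) +
             var(st$non_adhesive) / length(st$non_adhesive))
  expect_lt(abs(mean(st$cholesterol) - mean(st$non_adhesive)), 3 * se)
})

test_that("stratified comparison is skipped when a stratum is empty", {
  an <- structure(list(
    channels = list(E_pm = matrix(10, 2, 2)),
    strata = matrix("indeterminate", 2, 2)), class = "fv_analysis")
  st <- stratified_pm_elasticity(an)
  expect_true(st$skipped)
  expect_null(st$test)
})

test_that("percentage decreases match the printed before/after values", {
  expect_equal(percent_change(37.5, 15.9), 57.6, tolerance = 1e-10)
  expect_equal(percent_change(6.1, 3.4), 44.26, tolerance = 1e-3)
  expect_equal(percent_change(13.4, 7.7), 42.54, tolerance = 1e-3)
  expect_equal(percent_change(4.9, 3.6), 26.53, tolerance = 1e-3)
  expect_equal(percent_change(5, 5), 0)
  expect_error(percent_change(0, 1), "before")
})

test_that("fold changes match the printed modulus ratios", {
  expect_equal(fold_change(10.7, 5.3), 2.019, tolerance = 1e-3)
  expect_equal(fold_change(10.7, 3.7), 2.892, tolerance = 1e-3)
  expect_equal(fold_change(7, 7), 1)
  expect_error(fold_change(1, 0), "b")
})
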