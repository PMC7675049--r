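# run code under a temporary RNG state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Deterministic per-pixel sub-seed
#'
#' Hash of (seed, row, col) used to give every pixel of a simulated map its
#' own reproducible random stream, independent of traversal order:
#' `(seed * 48271 + row * 69621 + col * 40014) mod (2^31 - 1)`.
#'
#' @param seed integer master seed (taken mod 2^31 - 1).
#' @param row,col 1-based pixel coordinates.
#' @return An integer sub-seed in \[0, 2^31 - 2\].
#' @export
sub_seed <- function(seed, row, col) {
  m <- 2147483647
  as.integer((((seed %% m) * 48271) %% m + row * 69621 + col * 40014) %% m)
}

#' Build a synthetic ground-truth scene
#'
#' Generates the spatial ground truth a force-volume simulation samples from:
#' a clustered domain mask (random connected blobs with a truncated power-law
#' size distribution, grown until the target coverage is reached), a
#' two-valued plasma-membrane elasticity field (one value inside domains, one
#' outside), a uniform cortex elasticity field, and the per-pixel binding and
#' rupture parameters.
#'
#' Defaults emulate the structure reported for malignant mammary epithelial
#' cells imaged with a cholesterol-binding toxin probe: ~27.5% domain
#' coverage, PM moduli of 13.1 kPa inside versus 9.0 kPa outside domains over
#' a 15.9 kPa cortex, rupture forces of about 130 +/- 35 pN (truncated
#' positive; raise `rupture_min` to emulate a gated population), sub-20 pN
#' force noise, and ~100 nm pixels. A tethered pixel whose drawn rupture
#' force or distance falls below the specificity gates is ground-truth
#' non-specific; [scene_specific_truth()] gives the eligible fraction.
#'
#' @param rows,cols grid dimensions.
#' @param coverage target domain area fraction in \[0, 0.95\].
#' @param e_pm_in,e_pm_out PM Young's modulus inside/outside domains (kPa).
#' @param e_cortex cortex Young's modulus (kPa).
#' @param p_bind probability that a domain pixel carries a tether event.
#' @param rupture_mean,rupture_sd,rupture_min rupture-force distribution (pN).
#' @param lc_range tether contour-length range (nm), drawn uniformly.
#' @param lp tether persistence length (nm).
#' @param noise_sd Gaussian force noise SD (pN).
#' @param drift baseline drift polynomial coefficients (c0, c1, c2) in pN,
#'   pN/nm, pN/nm^2.
#' @param z0 piezo coordinate of the surface (nm).
#' @param blob_max,blob_power domain-size distribution: sizes 1..blob_max with
#'   probability proportional to size^-blob_power.
#' @param seed integer seed (recorded in the scene).
#' @return Object of class `synthetic_scene`.
#' @examples
#' sc <- build_scene(16, 16, coverage = 0.2, seed = 1)
#' mean(sc$domain_mask)
#' @export
build_scene <- function(rows = 64, cols = 64, coverage = 0.275,
                        e_pm_in = 13.1, e_pm_out = 9.0, e_cortex = 15.9,
                        p_bind = 1, rupture_mean = 130, rupture_sd = 35,
                        rupture_min = 0, lc_range = c(10, 40), lp = 0.38,
                        noise_sd = 15, drift = c(2, 0.01, 2e-5), z0 = 200,
                        blob_max = 64, blob_power = 1.8, seed) {
  if (missing(seed)) stop("build_scene: a seed is required", call. = FALSE)
  if (coverage < 0 || coverage > 0.95)
    stop("build_scene: coverage must be in [0, 0.95]", call. = FALSE)
  if (p_bind < 0 || p_bind > 1)
    stop("build_scene: p_bind must be in [0, 1]", call. = FALSE)
  mask <- matrix(FALSE, rows, cols)
  with_seed(seed, {
    target <- round(coverage * rows * cols)
    size_max <- min(blob_max, rows * cols)
    size_p <- (seq_len(size_max))^(-blob_power)
    dr <- c(-1L, 1L, 0L, 0L); dc <- c(0L, 0L, -1L, 1L)
    guard <- 0L
    while (sum(mask) < target) {
      guard <- guard + 1L
      if (guard > 100L * (target + 1L))
        stop("build_scene: coverage target unreachable", call. = FALSE)
      size <- sample.int(size_max, 1L, prob = size_p)
      blob <- matrix(c(sample.int(rows, 1L), sample.int(cols, 1L)), 1L)
      while (nrow(blob) < size) {
        nb <- cbind(rep(blob[, 1L], each = 4L) + dr,
                    rep(blob[, 2L], each = 4L) + dc)
        nb <- nb[nb[, 1L] >= 1L & nb[, 1L] <= rows &
                 nb[, 2L] >= 1L & nb[, 2L] <= cols, , drop = FALSE]
        nb <- nb[!(nb[, 1L] + rows * nb[, 2L]) %in%
                   (blob[, 1L] + rows * blob[, 2L]), , drop = FALSE]
        if (!nrow(nb)) break
        blob <- rbind(blob, nb[sample.int(nrow(nb), 1L), ])
      }
      mask[blob] <- TRUE
    }
  })
  e_pm <- matrix(e_pm_out, rows, cols)
  e_pm[mask] <- e_pm_in
  structure(list(
    rows = rows, cols = cols,
    domain_mask = mask,
    e_pm_true = e_pm,
    e_cortex_true = matrix(e_cortex, rows, cols),
    coverage_target = coverage,
    coverage_realized = mean(mask),
    p_bind = p_bind,
    rupture_mean = rupture_mean, rupture_sd = rupture_sd,
    rupture_min = rupture_min,
    lc_range = lc_range, lp = lp,
    noise_sd = noise_sd, drift = drift, z0 = z0,
    blob_max = blob_max, blob_power = blob_power,
    seed = seed
  ), class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("Synthetic scene %dx%d: coverage %.3f (target %.3f), E_pm %g/%g kPa (in/out), E_cortex %g kPa, seed %s\n",
              x$rows, x$cols, x$coverage_realized, x$coverage_target,
              max(x$e_pm_true), min(x$e_pm_true), x$e_cortex_true[1L], x$seed))
  invisible(x)
}

#' Per-pixel generation truth
#'
#' Extracts everything [simulate_curve()] needs to generate one pixel of a
#' scene.
#'
#' @param scene a [build_scene()] result.
#' @param row,col pixel coordinates (1-based).
#' @return A list with the pixel's elastic moduli, domain membership, and the
#'   scene's event/noise/drift parameters.
#' @export
pixel_truth <- function(scene, row, col) {
  list(e_pm = scene$e_pm_true[row, col],
       e_cortex = scene$e_cortex_true[row, col],
       in_domain = scene$domain_mask[row, col],
       p_bind = scene$p_bind,
       rupture_mean = scene$rupture_mean, rupture_sd = scene$rupture_sd,
       rupture_min = scene$rupture_min,
       lc_range = scene$lc_range, lp = scene$lp,
       noise_sd = scene$noise_sd, drift = scene$drift, z0 = scene$z0)
}

# clean two-layer contact response on a shared piezo grid: membrane modulus
# up to pm_boundary, then force-continuous switch to the cortex modulus
# (incremental stiffness; force accumulates across the boundary)
contact_template <- function(e_pm, e_cortex, acq, z0, n_samples,
                             pm_boundary = 50, bottom_effect = FALSE,
                             h = 50) {
  R <- acq$tip_radius; nu <- acq$poisson_ratio
  kp <- k_pn_per_nm(acq$spring_constant)
  setp <- acq$setpoint_force
  fpm <- function(d) if (bottom_effect) bottom_effect_force(e_pm, R, d, h)
  else hertz_force(e_pm, R, d, nu)
  C_cx <- hertz_prefactor(e_cortex, R, nu)
  f50 <- fpm(pm_boundary)
  fc <- function(d) ifelse(d <= pm_boundary, fpm(d),
                           f50 + C_cx * (d^1.5 - pm_boundary^1.5))
  dmax <- if (setp <= f50) {
    uniroot(function(d) fpm(d) - setp, c(0, pm_boundary), tol = 1e-10)$root
  } else {
    ((setp - f50) / C_cx + pm_boundary^1.5)^(2 / 3)
  }
  dd <- seq(0, dmax, length.out = 1024L)
  fd <- fc(dd)
  zd <- z0 + dd + fd / kp
  zmax <- zd[length(zd)]
  z <- seq(0, zmax, length.out = n_samples)
  f <- numeric(n_samples)
  inc <- z >= z0
  f[inc] <- approx(zd, fd, xout = z[inc], rule = 2)$y
  list(z = z, force = f, zmax = zmax, dmax = dmax)
}

# tether (WLC) contribution on a piezo grid; returns negative forces between
# the contact point and the rupture position
tether_force <- function(z, z0, f_rup, lc, lp, kBT, kp) {
  x_rup <- wlc_extension_at(f_rup, lp, lc, kBT)
  xs <- seq(0, x_rup, length.out = 256L)
  fs <- c(0, wlc_force(xs[-1L], lp, lc, kBT))
  zs <- z0 - xs - fs / kp  # strictly decreasing in xs
  out <- numeric(length(z))
  sel <- z < z0 & z >= zs[length(zs)]
  if (any(sel))
    out[sel] <- -approx(rev(zs), rev(fs), xout = z[sel], rule = 2)$y
  list(force = out, x_rup = x_rup)
}

# event draw for one pixel (consumes the pixel RNG stream in a fixed order)
draw_event <- function(truth) {
  u <- runif(1)
  if (!isTRUE(truth$in_domain) || u >= truth$p_bind) return(NULL)
  f_rup <- -1
  repeat {
    f_rup <- rnorm(1, truth$rupture_mean, truth$rupture_sd)
    if (f_rup > max(truth$rupture_min, 0)) break
  }
  lc <- runif(1, truth$lc_range[1L], truth$lc_range[2L])
  list(f_rup = f_rup, lc = lc, lp = truth$lp)
}

#' Simulate one force curve from ground truth
#'
#' Forward model for one pixel: a two-layer elastic contact response
#' (membrane modulus up to 50 nm indentation, force-continuous transition to
#' the cortex modulus beyond), second-degree baseline drift, Gaussian force
#' noise, and - with probability `p_bind` on domain pixels - a worm-like-chain
#' tether on the retraction rupturing at a force drawn from the scene's
#' truncated normal distribution. The approach turns around at the
#' acquisition setpoint force.
#'
#' @param truth a [pixel_truth()] list.
#' @param acq an [acquisition_params()].
#' @param seed integer seed for this curve (see [sub_seed()]).
#' @param n_samples samples per segment (default 512).
#' @param bottom_effect,h use the finite-thickness contact model for the
#'   membrane layer of thickness `h` nm.
#' @param template optional precomputed clean contact response (internal,
#'   lets [simulate_map()] share templates across pixels).
#' @return A [force_curve()] with attribute `truth`: the generation record
#'   (`z0`, moduli, and the injected `event` with its rupture force `f_rup`,
#'   rupture distance `x_rup` and contour length `lc`, or `NULL`).
#' @examples
#' tr <- pixel_truth(build_scene(2, 2, coverage = 0, seed = 1), 1, 1)
#' fc <- simulate_curve(tr, acquisition_params(), seed = 7)
#' @export
simulate_curve <- function(truth, acq = acquisition_params(), seed = NULL,
                           n_samples = 512, bottom_effect = FALSE, h = 50,
                           template = NULL) {
  if (is.null(template))
    template <- contact_template(truth$e_pm, truth$e_cortex, acq, truth$z0,
                                 n_samples, bottom_effect = bottom_effect,
                                 h = h)
  kp <- k_pn_per_nm(acq$spring_constant)
  kBT <- .kB_pN_nm * acq$temperature
  dr <- truth$drift
  with_seed(seed, {
    ev <- draw_event(truth)
    n <- length(template$z)
    drift_f <- dr[1L] + dr[2L] * template$z + dr[3L] * template$z^2
    app_f <- template$force + drift_f +
      if (truth$noise_sd > 0) rnorm(n, sd = truth$noise_sd) else 0
    ret_clean <- template$force
    if (!is.null(ev)) {
      tet <- tether_force(template$z, truth$z0, ev$f_rup, ev$lc, ev$lp,
                          kBT, kp)
      ret_clean <- ret_clean + tet$force
      ev$x_rup <- tet$x_rup
    }
    ret_f <- ret_clean + drift_f +
      if (truth$noise_sd > 0) rnorm(n, sd = truth$noise_sd) else 0
    fc <- force_curve(cbind(template$z, app_f),
                      cbind(rev(template$z), rev(ret_f)), acq = acq)
    attr(fc, "truth") <- list(z0 = truth$z0, e_pm = truth$e_pm,
                              e_cortex = truth$e_cortex, event = ev)
    fc
  })
}

#' Simulate a full force-volume map
#'
#' Applies [simulate_curve()] to every pixel of a scene. Each pixel draws from
#' an independent random stream seeded by [sub_seed()]`(seed, row, col)`, so
#' the result is reproducible and independent of traversal order. The scene
#' and the realized per-pixel event list are stored as the map's ground truth.
#'
#' @param scene a [build_scene()] result.
#' @param acq an [acquisition_params()].
#' @param seed master seed; defaults to the scene's seed.
#' @param n_samples samples per segment.
#' @param bottom_effect,h optional finite-thickness contact generation.
#' @return A [force-volume map][fv_map()] whose `truth` field holds the scene
#'   and a data frame of injected events (`row`, `col`, `f_rup`, `x_rup`,
#'   `lc`).
#' @export
simulate_map <- function(scene, acq = acquisition_params(),
                         seed = scene$seed, n_samples = 512,
                         bottom_effect = FALSE, h = 50) {
  keys <- unique(as.vector(scene$e_pm_true))
  templates <- lapply(keys, function(e)
    contact_template(e, scene$e_cortex_true[1L], acq, scene$z0, n_samples,
                     bottom_effect = bottom_effect, h = h))
  names(templates) <- format(keys, digits = 15)
  curves <- vector("list", scene$rows * scene$cols)
  ev_rows <- list()
  for (r in seq_len(scene$rows)) {
    for (c in seq_len(scene$cols)) {
      truth <- pixel_truth(scene, r, c)
      tpl <- templates[[format(truth$e_pm, digits = 15)]]
      fc <- simulate_curve(truth, acq, seed = sub_seed(seed, r, c),
                           n_samples = n_samples, template = tpl,
                           bottom_effect = bottom_effect, h = h)
      fc$row <- r; fc$col <- c
      idx <- (r - 1L) * scene$cols + c
      curves[[idx]] <- fc
      ev <- attr(fc, "truth")$event
      if (!is.null(ev))
        ev_rows[[length(ev_rows) + 1L]] <-
          data.frame(row = r, col = c, f_rup = ev$f_rup, x_rup = ev$x_rup,
                     lc = ev$lc)
    }
  }
  events <- if (length(ev_rows)) do.call(rbind, ev_rows)
  else data.frame(row = integer(), col = integer(), f_rup = numeric(),
                  x_rup = numeric(), lc = numeric())
  fv_map(curves, scene$rows, scene$cols, acq,
         truth = list(scene = scene, events = events, seed = seed))
}

#' Ground-truth specific-event mask of a simulated map
#'
#' A pixel is ground-truth specific when its injected tether event meets the
#' printed specificity gates (rupture force above `min_force`, rupture
#' distance above `min_distance`). The mean of this mask is the scene's true
#' binding probability, the reference for recovery studies.
#'
#' @param map a [simulate_map()] result (must carry truth).
#' @param min_force,min_distance specificity gates (pN, nm).
#' @return Logical `rows x cols` matrix.
#' @export
scene_specific_truth <- function(map, min_force = 80, min_distance = 5) {
  if (is.null(map$truth))
    stop("scene_specific_truth: map carries no ground truth", call. = FALSE)
  ev <- map$truth$events
  m <- matrix(FALSE, map$rows, map$cols)
  if (nrow(ev)) {
    ok <- ev$f_rup > min_force & ev$x_rup > min_distance
    m[cbind(ev$row[ok], ev$col[ok])] <- TRUE
  }
  m
}
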