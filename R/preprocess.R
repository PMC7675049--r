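# Off-contact sample index sets: the given fraction of samples farthest from
# the surface, i.e. with the smallest piezo coordinate z.
off_contact_idx <- function(z, fraction) {
  n <- length(z)
  m <- floor(fraction * n)
  order(z)[seq_len(m)]
}

#' Correct baseline drift with a second-degree polynomial
#'
#' Fits a quadratic to the off-contact area of each segment (the fraction of
#' samples farthest from the surface) and subtracts it, removing the tilt and
#' bow sometimes present in raw FD curves.
#'
#' With `extrapolate = "hold"` (the default) the fitted polynomial is
#' subtracted over its fit range and its edge value is held constant beyond
#' it. Extrapolating a quadratic fitted on noisy data deep into the contact
#' region injects smooth spurious force of the same order as the shallow
#' indentation signal, whereas genuine drift varies little over the contact
#' region; holding the edge value removes the offset without that noise
#' amplification. `extrapolate = "full"` subtracts the polynomial everywhere.
#'
#' @param curve a [force_curve()].
#' @param off_contact_fraction fraction of samples used for the fit (default
#'   0.3); at least 16 samples are required.
#' @param extrapolate `"hold"` or `"full"`, see Details.
#' @param segments which segments to correct (default both).
#' @return The corrected `force_curve`, with a `baseline` attribute: per
#'   segment the polynomial coefficients (c0, c1, c2) and the fraction used.
#' @examples
#' z <- seq(0, 400, length.out = 256)
#' f <- 2 + 0.01 * z + 2e-5 * z^2
#' fc <- force_curve(cbind(z, f), cbind(rev(z), rev(f)))
#' cc <- correct_baseline(fc, extrapolate = "full")
#' max(abs(cc$retract$force)) < 1e-9
#' @export
correct_baseline <- function(curve, off_contact_fraction = 0.3,
                             extrapolate = c("hold", "full"),
                             segments = c("approach", "retract")) {
  extrapolate <- match.arg(extrapolate)
  if (off_contact_fraction <= 0 || off_contact_fraction > 0.9)
    stop("correct_baseline: off_contact_fraction must be in (0, 0.9]",
         call. = FALSE)
  fits <- attr(curve, "baseline")
  if (is.null(fits)) fits <- list()
  for (sn in segments) {
    s <- curve[[sn]]
    idx <- off_contact_idx(s$z, off_contact_fraction)
    if (length(idx) < 16L)
      stop("correct_baseline: fewer than 16 off-contact samples", call. = FALSE)
    zb <- s$z[idx]
    X <- cbind(1, zb, zb * zb)
    cf <- qr.coef(qr(X), s$force[idx])
    cf[is.na(cf)] <- 0
    z_edge <- max(zb)
    zeval <- if (extrapolate == "full") s$z else pmin(s$z, z_edge)
    base <- cf[1L] + cf[2L] * zeval + cf[3L] * zeval * zeval
    curve[[sn]]$force <- s$force - base
    fits[[sn]] <- list(degree = 2L, coefficients = unname(cf),
                       off_contact_fraction = off_contact_fraction,
                       z_edge = z_edge, extrapolate = extrapolate)
  }
  attr(curve, "baseline") <- fits
  curve
}

#' Estimate the force noise level of a curve
#'
#' The noise level is the standard deviation of the residuals about a
#' straight-line fit of the off-contact part of the retraction curve, so a
#' residual tilt does not inflate the estimate.
#'
#' @param curve a [force_curve()].
#' @param off_contact_fraction fraction of samples (farthest from the surface)
#'   treated as off-contact; at least 32 samples are required.
#' @param segment segment to use (default "retract").
#' @return An object of class `noise_estimate`: list with `sigma` (pN) and
#'   `n_samples`.
#' @examples
#' z <- seq(0, 400, length.out = 512)
#' set.seed(1)
#' f <- rnorm(512, sd = 15)
#' fc <- force_curve(cbind(z, f), cbind(rev(z), rev(f)))
#' estimate_noise(fc)$sigma
#' @export
estimate_noise <- function(curve, off_contact_fraction = 0.3,
                           segment = c("retract", "approach")) {
  segment <- match.arg(segment)
  s <- curve_segment(curve, segment)
  idx <- off_contact_idx(s$z, off_contact_fraction)
  if (length(idx) < 32L)
    stop("estimate_noise: fewer than 32 off-contact samples", call. = FALSE)
  zb <- s$z[idx]; fb <- s$force[idx]
  X <- cbind(1, zb)
  r <- qr.resid(qr(X), fb)
  sigma <- sqrt(sum(r * r) / (length(idx) - 2L))
  structure(list(sigma = sigma, n_samples = length(idx)),
            class = "noise_estimate")
}

#' @export
print.noise_estimate <- function(x, ...) {
  cat(sprintf("Noise estimate: sigma = %.2f pN (n = %d off-contact samples)\n",
              x$sigma, x$n_samples))
  invisible(x)
}

#' Locate the tip-sample contact point
#'
#' Deterministic two-piece scan: every candidate split point divides the
#' scored sample range into an off-contact part, modeled as a constant, and an
#' in-contact part modeled as the force-continuous two-layer contact response
#' (membrane prefactor up to the membrane window boundary, cortex prefactor
#' beyond; linear in both, solved per candidate) in the deflection-corrected
#' depth. All candidates are scored on the same sample range, so a split
#' placed too early or too late must mis-explain the contact rise. The
#' candidate minimizing the summed squared residuals (equivalently maximizing
#' the variance explained by the two-piece model) is refined by parabolic
#' interpolation of the residual profile. A soft membrane over a stiffer
#' cortex puts most of the contact-point information in the deeper rise,
#' which is why the in-contact model must be the layered one.
#'
#' The scan runs on the approach segment by default: on toxin-functionalized
#' tips the retraction carries adhesion dips near the contact point that would
#' bias a least-squares split.
#'
#' @param curve a baseline-corrected [force_curve()].
#' @param noise optional [estimate_noise()] result; estimated internally when
#'   missing.
#' @param config an [fv_config()].
#' @return A list with `z0` (nm), `index` (sample index of the split),
#'   `no_contact` (flag: peak force below `contact_min_snr` times the noise
#'   SD), `sigma` and `method = "two-piece-scan"`.
#' @export
locate_contact_point <- function(curve, noise = NULL, config = fv_config(),
                                 center = NULL) {
  config <- as_fv_config(config)
  if (is.null(noise)) noise <- estimate_noise(curve, config$off_contact_fraction)
  seg <- curve_segment(curve, config$contact_segment)
  z <- seg$z; f <- seg$force
  if (z[1L] > z[length(z)]) { z <- rev(z); f <- rev(f) }
  n <- length(z)
  sigma <- noise$sigma
  if (max(f) < config$contact_min_snr * max(sigma, .Machine$double.eps))
    return(list(z0 = NA_real_, index = NA_integer_, no_contact = TRUE,
                sigma = sigma, method = "two-piece-scan"))
  # coarse anchor: first sustained rise above the detection floor (5 sigma,
  # with a small relative floor so residual drift on near-noise-free curves
  # does not trigger), then scan a window of candidates around it
  thr <- max(5 * sigma, 0.02 * max(f))
  above <- f > thr
  run <- which(above & c(above[-1L], FALSE) & c(above[-(1:2)], FALSE, FALSE))
  anchor <- if (length(run)) run[1L] else which.max(f)
  dz <- (z[n] - z[1L]) / (n - 1L)
  if (is.null(center)) {
    lo <- max(2L, anchor - as.integer(ceiling(150 / dz)))
    hi <- min(n - 8L, anchor + as.integer(ceiling(30 / dz)))
  } else {
    # refinement pass: scan only around a previous estimate
    ic <- which.min(abs(z - center))
    lo <- max(2L, ic - as.integer(ceiling(20 / dz)))
    hi <- min(n - 8L, ic + as.integer(ceiling(20 / dz)))
  }
  if (hi < lo) hi <- lo
  # score all candidates on the same sample range, covering the depth over
  # which the two-layer model is meaningful
  i_end <- min(n, anchor + as.integer(ceiling(
    (config$cortex_window_nm[2L] + 50) / dz)))
  kp <- k_pn_per_nm(curve$acq$spring_constant)
  res <- cpp_contact_scan(z, f, lo - 1L, hi - 1L, i_end - 1L, kp,
                          config$pm_window_nm)
  idx <- res$index + 1L
  list(z0 = res$z0, index = idx, no_contact = FALSE, sigma = sigma,
       method = "two-piece-scan")
}
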