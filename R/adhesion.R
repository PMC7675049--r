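#' Worm-like chain (interpolation formula) force-extension model
#'
#' Entropic elasticity of a polymer tether (here the PEG linker carrying the
#' toxin probe): `F = (kBT/Lp) * (1/4 (1 - x/Lc)^-2 - 1/4 + x/Lc)`.
#'
#' @param x extension(s) in nm; requires `0 <= x < Lc`.
#' @param Lp persistence length in nm.
#' @param Lc contour length in nm.
#' @param kBT thermal energy in pN nm (default: 310 K, cell-culture
#'   temperature, 4.28 pN nm).
#' @return Force(s) in pN (positive = tensile).
#' @examples
#' wlc_force(15, Lp = 0.38, Lc = 30)  # half extension: 1.25 kBT/Lp
#' @export
wlc_force <- function(x, Lp, Lc, kBT = .kB_pN_nm * 310) {
  if (Lp <= 0 || Lc <= 0 || Lp >= Lc)
    stop("wlc_force: need 0 < Lp < Lc", call. = FALSE)
  if (kBT <= 0) stop("wlc_force: kBT must be > 0", call. = FALSE)
  if (any(x < 0) || any(x >= Lc))
    stop("wlc_force: extension must satisfy 0 <= x < Lc", call. = FALSE)
  t <- x / Lc
  (kBT / Lp) * (0.25 * (1 - t)^-2 - 0.25 + t)
}

# extension at which the WLC reaches force f (inverse of wlc_force)
wlc_extension_at <- function(f, Lp, Lc, kBT = .kB_pN_nm * 310) {
  uniroot(function(x) wlc_force(x, Lp, Lc, kBT) - f,
          lower = 0, upper = Lc * (1 - 1e-9), tol = 1e-10)$root
}

#' Detect rupture candidates on a retraction curve
#'
#' Scans the off-contact part of the baseline-corrected retraction (in time
#' order) for adhesion ruptures: local minima of the running-mean smoothed
#' force that fall below `-rupture_snr * sigma` and return toward the baseline
#' within 5 samples. Each candidate reports the rupture force (magnitude of
#' the local raw force minimum) and the rupture distance, i.e. the
#' deflection-corrected tip-sample separation `(z0 - z) + F/k` at the minimum.
#' Candidates are ordered by distance.
#'
#' @param curve a baseline-corrected [force_curve()].
#' @param noise an [estimate_noise()] result (or list with `sigma`).
#' @param z0 contact point in nm (from [locate_contact_point()]).
#' @param config an [fv_config()].
#' @return A list of candidate events, each a list of class `adhesion_event`:
#'   `rupture_force` (pN), `rupture_distance` (nm), `index` (sample index in
#'   the retraction), `wlc` (`NULL` until validated), `wlc_reject` (reason or
#'   `NULL`), `specific` (`NA` until classified). May be empty.
#' @export
detect_ruptures <- function(curve, noise, z0, config = fv_config()) {
  config <- as_fv_config(config)
  s <- curve$retract
  sigma <- max(noise$sigma, .Machine$double.eps)
  kp <- k_pn_per_nm(curve$acq$spring_constant)
  # time order: retract z is stored descending (pulling away)
  idx <- cpp_detect_ruptures(s$force, s$z, z0, sigma, config$rupture_snr,
                             as.integer(config$rupture_smooth))
  if (!length(idx)) return(list())
  ev <- lapply(idx + 1L, function(i) {
    f <- s$force[i]
    dist <- (z0 - s$z[i]) + f / kp
    structure(list(rupture_force = abs(f),
                   rupture_distance = max(dist, 0),
                   index = i, wlc = NULL, wlc_reject = NULL,
                   specific = NA), class = "adhesion_event")
  })
  ev[order(vapply(ev, `[[`, numeric(1), "rupture_distance"))]
}

#' Validate a rupture candidate against the worm-like chain model
#'
#' Fits the tether extension profile between the contact crossing (or the
#' preceding rupture) and the rupture with the WLC model (bounded
#' Levenberg-Marquardt over persistence and contour length). Accepted events
#' also get
#' a finite-sampling refinement of the rupture force: the fitted tether force
#' at the last tethered sample plus half a sample's force rise along the
#' model. The event is accepted when the fit RMS is
#' below `wlc_rms_factor * sigma` and the fitted contour length falls inside
#' `wlc_lc_bounds_nm`; otherwise a rejection reason is recorded
#' (`"too_short"`, `"rms"`, `"lc_range"`, or `"no_convergence"`).
#'
#' @param curve the baseline-corrected [force_curve()].
#' @param event an [detect_ruptures()] candidate.
#' @param noise an [estimate_noise()] result.
#' @param z0 contact point in nm.
#' @param config an [fv_config()].
#' @param start_index optional first retraction sample of the tether segment
#'   (set past the preceding rupture for multi-event curves); defaults to the
#'   contact crossing.
#' @return The event with `wlc` set to a list of class `wlc_params`
#'   (`Lp`, `Lc`, `x0` in nm, `kBT` in pN nm, `rms` in pN, `n`) on
#'   acceptance, or with `wlc_reject` set to the reason.
#' @export
validate_wlc <- function(curve, event, noise, z0, config = fv_config(),
                         start_index = NULL) {
  config <- as_fv_config(config)
  s <- curve$retract
  sigma <- max(noise$sigma, .Machine$double.eps)
  kp <- k_pn_per_nm(curve$acq$spring_constant)
  kBT <- .kB_pN_nm * curve$acq$temperature
  i_rup <- event$index
  # tether segment: from the contact crossing (or just past the preceding
  # rupture, for multi-event curves) to the rupture
  i0 <- if (!is.null(start_index)) max(start_index, 1L)
  else {
    w <- which(s$z < z0)
    # pre-crossing samples anchor the extension offset of the fit (the
    # located contact point carries a few nm of uncertainty)
    if (length(w)) max(w[1L] - 16L, 1L) else i_rup
  }
  if (i0 >= i_rup) {
    event$wlc_reject <- "too_short"
    return(event)
  }
  seg <- i0:i_rup
  # extension = deflection-corrected separation; keep the zero-force apron
  # but exclude in-contact (positive-force) samples
  x <- (z0 - s$z[seg]) + s$force[seg] / kp
  y <- -s$force[seg]
  keep <- x > -14 & s$force[seg] < 2 * sigma
  n_geo <- sum(x > 0)
  x <- x[keep]; y <- y[keep]
  if (length(x) < config$wlc_min_samples) {
    event$wlc_reject <- "too_short"
    return(event)
  }
  lcb <- config$wlc_lc_bounds_nm
  lpb <- config$wlc_lp_bounds_nm
  xmax <- max(x)
  lc_lo <- 3
  lc_hi <- max(lcb[2L] * 2, xmax * 2)
  lc0 <- min(max(xmax / 0.85, 5), lc_hi * 0.9)
  fit <- cpp_wlc_fit(x, y, kBT, config$wlc_lp_init_nm, lc0,
                     lpb[1L], lpb[2L], lc_lo, lc_hi, 0, 0)
  if (!fit$converged) {
    event$wlc_reject <- "no_convergence"
    return(event)
  }
  # tether-sample count: the geometric count (from the located contact point)
  # and the fit-anchored count (from the fitted extension offset) each err in
  # one direction under contact-point error, so take the larger; genuinely
  # short segments fail both
  n_teth <- max(sum(x - fit$x0 > 0), n_geo)
  if (n_teth < config$wlc_min_samples) {
    event$wlc_reject <- "too_short"
    return(event)
  }
  wlc <- structure(list(Lp = fit$lp, Lc = fit$lc, x0 = fit$x0, kBT = kBT,
                        rms = fit$rms, n = n_teth), class = "wlc_params")
  if (fit$rms >= config$wlc_rms_factor * max(sigma, 0.1)) {
    event$wlc_reject <- "rms"
    event$wlc_candidate <- wlc
    return(event)
  }
  if (fit$lc < lcb[1L] || fit$lc > lcb[2L]) {
    event$wlc_reject <- "lc_range"
    event$wlc_candidate <- wlc
    return(event)
  }
  event$wlc <- wlc
  # finite-sampling correction: the last sampled point sits up to one sample
  # short of the true rupture on a steep tether, so the raw force minimum
  # underestimates the rupture force by about half a sample's force rise
  # along the model; dF/dz = W'/(1 + W'/k) with W' the WLC stiffness
  # rupture-force refinement: read the force at the last tethered sample from
  # a physics-constrained fit (persistence length fixed at the linker value,
  # so the noisy endpoint cannot drag the model), then add the expected force
  # rise over the unobserved gap to the actual break. The break position is
  # uniform within one sample of piezo travel past the last tethered sample,
  # and the tether model diverges there, so the expectation is taken by
  # integrating the model force over that piezo interval rather than
  # linearizing it.
  dz_loc <- if (i_rup > 1L) abs(s$z[i_rup] - s$z[i_rup - 1L]) else 0
  lpc <- fit$lp
  wlc_m <- function(xx) {
    t <- pmin(pmax(xx, 0) / fit$lc, 0.995)
    (kBT / lpc) * (0.25 * (1 - t)^-2 - 0.25 + t)
  }
  x_last <- max(event$rupture_distance - fit$x0, 0)
  f_last <- wlc_m(x_last)
  xs <- seq(x_last, min(x_last + 2 * dz_loc + 2, 0.995 * fit$lc),
            length.out = 64L)
  fs_m <- wlc_m(xs)
  dz_used <- (xs - x_last) + (fs_m - f_last) / kp
  zg <- seq(0, dz_loc, length.out = 17L)[-1L]
  f_gap <- approx(dz_used, fs_m, xout = pmin(zg, max(dz_used)), rule = 2)$y
  event$rupture_force_raw <- event$rupture_force
  event$rupture_force <- mean(f_gap)
  event
}

#' @export
print.wlc_params <- function(x, ...) {
  cat(sprintf("WLC fit: Lp = %.3g nm, Lc = %.3g nm, rms = %.2f pN (n = %d)\n",
              x$Lp, x$Lc, x$rms, x$n))
  invisible(x)
}

#' Classify an adhesion event as specific or not
#'
#' An unbinding event counts as specific when its rupture force exceeds
#' `min_force`, its rupture distance from the contact point exceeds
#' `min_distance`, and its extension profile was validated by the WLC model.
#'
#' @param event an [adhesion_event][detect_ruptures()] (after
#'   [validate_wlc()]).
#' @param min_force specificity force gate in pN (default 80).
#' @param min_distance specificity distance gate in nm (default 5).
#' @return The event with `specific` set to `TRUE`/`FALSE`.
#' @export
classify_specific <- function(event, min_force = 80, min_distance = 5) {
  event$specific <- isTRUE(event$rupture_force > min_force) &&
    isTRUE(event$rupture_distance > min_distance) &&
    !is.null(event$wlc)
  event
}

#' @export
print.adhesion_event <- function(x, ...) {
  cat(sprintf("Adhesion event: %.1f pN at %.1f nm, %s%s\n",
              x$rupture_force, x$rupture_distance,
              if (is.na(x$specific)) "unclassified"
              else if (x$specific) "specific" else "non-specific",
              if (!is.null(x$wlc)) sprintf(" (WLC Lc = %.1f nm)", x$wlc$Lc)
              else if (!is.null(x$wlc_reject))
                sprintf(" (WLC rejected: %s)", x$wlc_reject)
              else ""))
  invisible(x)
}

#' Stratify a pixel by its adhesion events
#'
#' Pixels are assigned to the cholesterol-enriched stratum when a specific
#' unbinding event above `cholesterol_min_force_pN` (default 100 pN) is
#' recorded, to the non-adhesive stratum when no candidate exceeds
#' `nonadhesive_max_force_pN` (default 30 pN; no candidates at all counts),
#' and are otherwise indeterminate and excluded from stratified statistics.
#'
#' @param events list of classified events at one pixel (possibly empty).
#' @param config an [fv_config()].
#' @return One of `"cholesterol"`, `"non_adhesive"`, `"indeterminate"`.
#' @export
stratify_pixel <- function(events, config = fv_config()) {
  config <- as_fv_config(config)
  if (!length(events)) return("non_adhesive")
  forces <- vapply(events, `[[`, numeric(1), "rupture_force")
  spec <- vapply(events, function(e) isTRUE(e$specific), logical(1))
  if (any(spec & forces > config$cholesterol_min_force_pN)) return("cholesterol")
  if (all(forces < config$nonadhesive_max_force_pN)) return("non_adhesive")
  "indeterminate"
}
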