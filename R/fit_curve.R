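#' Fit one force curve end to end
#'
#' Runs the full per-pixel analysis: baseline correction, noise estimation,
#' contact-point location, depth-segmented elasticity, rupture-event detection
#' with WLC validation, specificity classification and stratification.
#'
#' `prepare_curve()` runs the shared first stages only - baseline correction
#' (with a second, contact-aware pass that widens the off-contact fit range
#' once the contact point is roughly known), noise estimation, and
#' contact-point location - and returns the corrected curve, the
#' [estimate_noise()] result and the [locate_contact_point()] result. It is
#' used by both `fit_curve()` and [pooled_moduli()].
#'
#' @param curve a raw [force_curve()].
#' @param config an [fv_config()].
#' @return For `fit_curve()`, an object of class `fd_fit`: `noise`
#'   ([estimate_noise()]), `z0`, `no_contact`, `mechanics`
#'   ([segmented_moduli()] or `NULL`), `events` (classified candidate list),
#'   `stratum`, `row`, `col`. For `prepare_curve()`, a list with `corrected`,
#'   `noise`, `cp`.
#' @examples
#' tr <- pixel_truth(build_scene(2, 2, coverage = 0, seed = 1), 1, 1)
#' fit <- fit_curve(simulate_curve(tr, seed = 3))
#' fit$mechanics$E_pm
#' @export
fit_curve <- function(curve, config = fv_config()) {
  config <- as_fv_config(config)
  prep <- prepare_curve(curve, config)
  corrected <- prep$corrected
  noise <- prep$noise
  cp <- prep$cp
  if (cp$no_contact) {
    return(structure(list(noise = noise, z0 = NA_real_, no_contact = TRUE,
                          mechanics = NULL, events = list(),
                          stratum = NA_character_,
                          row = curve$row, col = curve$col),
                     class = "fd_fit"))
  }
  # contact anchoring: remove the residual local baseline offset just before
  # contact (estimated on the approach, whose pre-contact region is free of
  # tether forces) so the through-origin membrane-window fit is unbiased
  za <- corrected$approach$z
  sel <- za >= cp$z0 - 40 & za <= cp$z0 - 5
  if (sum(sel) >= 8) {
    off_local <- mean(corrected$approach$force[sel])
    corrected[[config$fit_segment]]$force <-
      corrected[[config$fit_segment]]$force - off_local
  }
  ind <- to_indentation(corrected, cp$z0, segment = config$fit_segment)
  mech <- segmented_moduli(ind, curve$acq$tip_radius,
                           curve$acq$poisson_ratio, config)
  events <- detect_ruptures(corrected, noise, cp$z0, config)
  if (length(events)) {
    idx <- vapply(events, `[[`, integer(1), "index")
    for (k in seq_along(events)) {
      prev <- idx[idx < idx[k]]
      start <- if (length(prev)) max(prev) + 2L else NULL
      e <- validate_wlc(corrected, events[[k]], noise, cp$z0, config,
                        start_index = start)
      events[[k]] <- classify_specific(e, config$specific_min_force_pN,
                                       config$specific_min_distance_nm)
    }
  }
  structure(list(noise = noise, z0 = cp$z0, no_contact = FALSE,
                 mechanics = mech, events = events,
                 stratum = stratify_pixel(events, config),
                 row = curve$row, col = curve$col),
            class = "fd_fit")
}

#' @rdname fit_curve
#' @export
prepare_curve <- function(curve, config = fv_config()) {
  config <- as_fv_config(config)
  corrected <- correct_baseline(curve, config$off_contact_fraction,
                                config$baseline_extrapolate)
  noise <- estimate_noise(corrected, config$off_contact_fraction)
  cp <- locate_contact_point(corrected, noise, config)
  if (!cp$no_contact) {
    # second pass: re-fit the baseline on everything that is clearly
    # off-contact (the initial conservative fraction can leave a residual
    # drift ramp between its edge and the contact point); on the retraction
    # the margin additionally clears the possible tether region
    frac_a <- min(mean(curve$approach$z < cp$z0 - 15), 0.9)
    frac_r <- min(mean(curve$retract$z <
                         cp$z0 - (config$wlc_lc_bounds_nm[2L] + 20)), 0.9)
    if (frac_a > config$off_contact_fraction)
      corrected <- correct_baseline(curve, frac_a,
                                    config$baseline_extrapolate, "approach")
    if (frac_r > config$off_contact_fraction) {
      corrected <- correct_baseline(corrected, frac_r,
                                    config$baseline_extrapolate, "retract")
      noise <- estimate_noise(corrected, frac_r)
    }
    if (frac_a > config$off_contact_fraction ||
        frac_r > config$off_contact_fraction)
      cp <- locate_contact_point(corrected, noise, config, center = cp$z0)
  }
  list(corrected = corrected, noise = noise, cp = cp)
}

#' @export
print.fd_fit <- function(x, ...) {
  if (x$no_contact) {
    cat("FD curve fit: no contact detected (pixel excluded)\n")
    return(invisible(x))
  }
  cat(sprintf("FD curve fit: z0 = %.1f nm, sigma = %.1f pN\n", x$z0,
              x$noise$sigma))
  print(x$mechanics)
  nspec <- sum(vapply(x$events, function(e) isTRUE(e$specific), logical(1)))
  cat(sprintf("  events: %d candidate(s), %d specific; stratum: %s\n",
              length(x$events), nspec, x$stratum))
  invisible(x)
}
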