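#' Pooled (global) two-layer elasticity fit for a group of pixels
#'
#' Per-curve elasticity estimates at live-cell noise levels are dominated by
#' the uncertainty of each curve's contact point: the membrane prefactor and
#' the contact point are strongly correlated, so per-pixel moduli are noisy
#' and - once truncated at zero or selected for convergence - upward biased.
#' `pooled_moduli()` instead fits one pair of layer moduli to all curves of a
#' group simultaneously, with a per-curve contact point:
#'
#' \deqn{F_{ij} = C_{pm} a(\delta_{ij}) + C_{cx} b(\delta_{ij}) +
#'       \beta \delta_{ij}}
#'
#' where `a`, `b` are the force-continuous two-layer basis functions of
#' [segmented_moduli()], `delta_ij` the deflection-corrected depth of sample
#' `j` in curve `i` given that curve's contact point, and `beta` a shared
#' nuisance ramp absorbing residual baseline drift; residual per-curve
#' baseline offsets are removed beforehand with the approach-side pre-contact
#' anchor of [fit_curve()].
#' The fit alternates (a) shared-coefficient least squares on the in-contact
#' retraction samples (layer prefactors clamped nonnegative), (b) a global
#' contact-shift line search (the slow, strongly correlated mode of the
#' likelihood), and (c) per-curve contact-point refinement on the approach
#' segment with a profiled per-curve offset.
#'
#' Because the moduli are shared, each contact point is well identified, and
#' the pooled moduli are close to unbiased even where per-pixel estimates are
#' not; use it whenever a group mean (a cell, a stratum, a condition) is the
#' quantity of interest.
#'
#' @param map a [fv_map()].
#' @param config an [fv_config()].
#' @param pixels optional logical `rows x cols` matrix selecting the pixel
#'   group (default: all pixels with curves).
#' @param sweeps number of alternation sweeps (default 12).
#' @param prep optional precomputed list of [prepare_curve()] results (row
#'   major), to avoid re-running the per-curve stages.
#' @return Object of class `pooled_fit`: `E_pm`, `E_cortex` (kPa), `z0`
#'   (named numeric, refined contact point per pixel), `n_curves`, `nuisance`
#'   (ramp), `rms` (pN).
#' @export
pooled_moduli <- function(map, config = fv_config(), pixels = NULL,
                          sweeps = 12, prep = NULL) {
  config <- as_fv_config(config)
  acq <- map$acq
  kp <- k_pn_per_nm(acq$spring_constant)
  R <- acq$tip_radius
  nu <- acq$poisson_ratio
  bnd <- config$pm_window_nm
  unit_pm <- function(dd)
    if (isTRUE(config$bottom_effect))
      bottom_effect_force(1, R, dd, config$layer_thickness_nm)
    else hertz_force(1, R, dd, nu)
  b15 <- bnd^1.5

  appr <- retr <- list()
  z0s <- c()
  keys <- c()
  for (r in seq_len(map$rows)) {
    for (c in seq_len(map$cols)) {
      if (!is.null(pixels) && !isTRUE(pixels[r, c])) next
      fc <- map_curve(map, r, c)
      if (is.null(fc)) next
      p <- if (!is.null(prep)) prep[[(r - 1L) * map$cols + c]]
      else prepare_curve(fc, config)
      if (is.null(p) || p$cp$no_contact) next
      appr[[length(appr) + 1L]] <- p$corrected$approach
      retr[[length(retr) + 1L]] <- p$corrected$retract
      z0s <- c(z0s, p$cp$z0)
      keys <- c(keys, sprintf("%d,%d", r, c))
    }
  }
  n <- length(z0s)
  if (n < 2L)
    stop("pooled_moduli: need at least 2 analysable curves", call. = FALSE)
  names(z0s) <- keys

  # per-curve local offset anchor from the approach (tether-free) pre-contact
  # band, as in fit_curve()
  offs <- vapply(seq_len(n), function(i) {
    za <- appr[[i]]$z
    s <- za >= z0s[i] - 40 & za <= z0s[i] - 5
    if (sum(s) >= 8) mean(appr[[i]]$force[s]) else 0
  }, numeric(1))

  # fixed in-contact retraction sample sets (tether-free side excluded)
  sel <- lapply(seq_len(n), function(i) retr[[i]]$z > z0s[i])
  zr <- unlist(lapply(seq_len(n), function(i) retr[[i]]$z[sel[[i]]]))
  fr <- unlist(lapply(seq_len(n), function(i)
    retr[[i]]$force[sel[[i]]] - offs[i]))
  nr <- vapply(sel, sum, integer(1))

  design <- function(z0v) {
    d <- pmax((zr - rep(z0v, nr)) - fr / kp, 0)
    cbind(unit_pm(pmin(d, bnd)), pmax(d^1.5 - b15, 0), 1, d)
  }
  fitC <- function(z0v) {
    X <- design(z0v)
    cf <- qr.coef(qr(X), fr)
    cf[is.na(cf)] <- 0
    cf[1L] <- max(cf[1L], 0)
    cf[2L] <- max(cf[2L], 0)
    list(cf = cf, rss = sum((fr - X %*% cf)^2))
  }
  shift_sse <- function(s) {
    X <- design(z0s + s)
    cf <- qr.coef(qr(X), fr)
    cf[is.na(cf)] <- 0
    sum((fr - X %*% cf)^2)
  }
  fit <- fitC(z0s)
  for (it in seq_len(sweeps)) {
    z0s_prev <- z0s
    s_opt <- optimize(shift_sse, c(-6, 6))$minimum
    z0s <- z0s + s_opt
    fit <- fitC(z0s)
    cf <- fit$cf
    for (i in seq_len(n)) {
      z <- appr[[i]]$z; f <- appr[[i]]$force
      win <- z > z0s[i] - 30
      zz <- z[win]; ff <- f[win]
      sse <- function(z0) {
        d <- pmax((zz - z0) - ff / kp, 0)
        mod <- cf[1L] * unit_pm(pmin(d, bnd)) +
          cf[2L] * pmax(d^1.5 - b15, 0) + cf[4L] * d
        rr <- ff - mod
        sum((rr - mean(rr))^2)  # per-curve offset profiled out
      }
      z0s[i] <- optimize(sse, c(z0s[i] - 8, z0s[i] + 8))$minimum
    }
    fit <- fitC(z0s)
    if (max(abs(z0s - z0s_prev)) < 0.02) break
  }
  cf <- fit$cf
  conv <- (3 / 4) * (1 - nu^2) / sqrt(R) * 1e3
  structure(list(
    E_pm = if (cf[1L] > 0) unname(cf[1L]) else NA_real_,
    E_cortex = if (cf[2L] > 0) unname(cf[2L] * conv) else NA_real_,
    z0 = z0s, n_curves = n,
    nuisance = c(offset = unname(cf[3L]), ramp = unname(cf[4L])),
    rms = sqrt(fit$rss / length(fr)),
    bottom_effect_used = isTRUE(config$bottom_effect)
  ), class = "pooled_fit")
}

#' @export
print.pooled_fit <- function(x, ...) {
  cat(sprintf("Pooled two-layer fit over %d curves\n", x$n_curves))
  cat(sprintf("  E_pm     = %.3g kPa%s\n", x$E_pm,
              if (x$bottom_effect_used) " (bottom-effect corrected)" else ""))
  cat(sprintf("  E_cortex = %.3g kPa\n", x$E_cortex))
  cat(sprintf("  rms = %.2f pN; nuisance offset %.2f pN, ramp %.4f pN/nm\n",
              x$rms, x$nuisance[1L], x$nuisance[2L]))
  invisible(x)
}
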