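# unit bridge: E [kPa] -> prefactor C in F[pN] = C * delta[nm]^(3/2)
# 1 kPa = 1e-3 pN/nm^2
hertz_prefactor <- function(E_kPa, R_nm, nu) {
  (4 / 3) * (E_kPa * 1e-3 / (1 - nu^2)) * sqrt(R_nm)
}

#' Hertz sphere-contact force
#'
#' Force on a spherical indenter of radius `R` at indentation `delta` into an
#' elastic half-space: `F = (4/3) * E/(1 - nu^2) * sqrt(R) * delta^(3/2)`.
#'
#' @param E Young's modulus in kPa.
#' @param R tip radius in nm.
#' @param delta indentation depth(s) in nm; must be >= 0.
#' @param nu Poisson ratio (default 0.5, incompressible).
#' @return Force(s) in pN.
#' @examples
#' hertz_force(5.3, 65, 50)  # ~26.9 pN
#' @export
hertz_force <- function(E, R, delta, nu = 0.5) {
  if (any(!is.finite(E)) || any(E <= 0)) stop("hertz_force: E must be > 0", call. = FALSE)
  if (!is.finite(R) || R <= 0) stop("hertz_force: R must be > 0", call. = FALSE)
  if (nu < 0 || nu > 0.5) stop("hertz_force: nu must be in [0, 0.5]", call. = FALSE)
  if (any(delta < 0)) stop("hertz_force: delta must be >= 0", call. = FALSE)
  hertz_prefactor(E, R, nu) * delta^1.5
}

#' Bottom-effect corrected sphere-contact force
#'
#' Finite-thickness correction for a soft layer of thickness `h` bonded to a
#' rigid support, for an incompressible sample (nu = 0.5):
#' `F = (16 E / 9) sqrt(R) delta^(3/2) * (1 + 0.884 a + 0.781 a^2 +
#' 0.386 a^3 + 0.0048 a^4)` with `a = sqrt(R delta) / h`. As `h` grows the
#' correction factor tends to 1 and the expression reduces to [hertz_force()]
#' with nu = 0.5 (note `(16/9) E = (4/3) E / (1 - 0.25)`).
#'
#' @param E Young's modulus in kPa.
#' @param R tip radius in nm.
#' @param delta indentation depth(s) in nm, >= 0.
#' @param h layer thickness in nm, > 0.
#' @return Force(s) in pN.
#' @examples
#' bottom_effect_force(10.7, 65, 50, h = 200) / hertz_force(10.7, 65, 50)
#' @export
bottom_effect_force <- function(E, R, delta, h) {
  if (!is.finite(h) || h <= 0) stop("bottom_effect_force: h must be > 0", call. = FALSE)
  if (any(!is.finite(E)) || any(E <= 0)) stop("bottom_effect_force: E must be > 0", call. = FALSE)
  if (!is.finite(R) || R <= 0) stop("bottom_effect_force: R must be > 0", call. = FALSE)
  if (any(delta < 0)) stop("bottom_effect_force: delta must be >= 0", call. = FALSE)
  a <- sqrt(R * delta) / h
  fac <- 1 + 0.884 * a + 0.781 * a^2 + 0.386 * a^3 + 0.0048 * a^4
  (16 * E * 1e-3 / 9) * sqrt(R) * delta^1.5 * fac
}

window_samples <- function(ind, window) {
  sel <- ind$delta > window[1L] & ind$delta <= window[2L]
  list(delta = ind$delta[sel], force = ind$force[sel], n = sum(sel))
}

#' Hertz modulus from the slope of the linearized contact model
#'
#' Least-squares fit of the Hertz sphere model over an indentation window.
#' The model is linear in the prefactor, `F = C * delta^(3/2)` with
#' `C = (4/3) E/(1-nu^2) sqrt(R)`, so the modulus comes from the regression
#' slope of force on `delta^(3/2)` (equivalent, noise-free, to the slope of
#' `F^(2/3)` versus `delta`, but well defined when noise drives individual
#' force samples negative). `method = "linearized"` fits `F^(2/3)` versus
#' `delta` directly, clipping negative forces at zero.
#'
#' Windows starting at zero depth are contact-anchored: the regression is
#' forced through the origin. Windows starting deeper get a free intercept,
#' which absorbs the force accumulated in the shallower layers: in any
#' force-continuous layered model the deep-window response is
#' `F = C_deep * delta^(3/2) + const`, so the slope isolates the deep layer's
#' modulus (see the package vignette).
#'
#' @param ind an [to_indentation()] curve.
#' @param window depth window `(lo, hi]` in nm.
#' @param R tip radius in nm.
#' @param nu Poisson ratio.
#' @param intercept force a free intercept (`TRUE`)/through-origin (`FALSE`);
#'   default: through-origin iff the window starts at 0.
#' @param method `"force"` (default) or `"linearized"`, see Details.
#' @return List of class `hertz_fit`: `E` (kPa, `NA` if the fit failed),
#'   `slope`, `rms` (pN), `n`, `window`, `converged`.
#' @examples
#' d <- seq(0.5, 200, by = 0.5)
#' ic <- structure(list(delta = d, force = hertz_force(10.7, 65, d),
#'                      z0 = 0, segment = "retract"),
#'                 class = "indentation_curve")
#' hertz_slope_fit(ic, c(0, 200), R = 65)$E
#' @export
hertz_slope_fit <- function(ind, window, R, nu = 0.5,
                            intercept = window[1L] > 0,
                            method = c("force", "linearized")) {
  method <- match.arg(method)
  w <- window_samples(ind, window)
  if (w$n < 8L)
    stop("hertz_slope_fit: fewer than 8 samples in the window", call. = FALSE)
  if (method == "force") {
    x <- w$delta^1.5
    y <- w$force
    if (intercept) {
      mx <- mean(x); my <- mean(y)
      sxx <- sum((x - mx)^2)
      slope <- sum((x - mx) * (y - my)) / sxx
      fitted <- my + slope * (x - mx)
    } else {
      slope <- sum(x * y) / sum(x * x)
      fitted <- slope * x
    }
    C <- slope
  } else {
    x <- w$delta
    y <- pmax(w$force, 0)^(2 / 3)
    if (intercept) {
      mx <- mean(x); my <- mean(y)
      slope <- sum((x - mx) * (y - my)) / sum((x - mx)^2)
      fitted <- my + slope * (x - mx)
    } else {
      slope <- sum(x * y) / sum(x * x)
      fitted <- slope * x
    }
    C <- if (slope > 0) slope^1.5 else slope
  }
  rms <- sqrt(mean((y - fitted)^2))
  if (!is.finite(C) || C <= 0) {
    return(structure(list(E = NA_real_, slope = slope, rms = rms, n = w$n,
                          window = window, converged = FALSE,
                          method = method), class = "hertz_fit"))
  }
  E <- C * (3 / 4) * (1 - nu^2) / sqrt(R) * 1e3
  structure(list(E = E, slope = slope, rms = rms, n = w$n, window = window,
                 converged = TRUE, method = method), class = "hertz_fit")
}

#' Modulus fit with the bottom-effect corrected model
#'
#' The corrected force is linear in E, so the least-squares modulus over the
#' window is closed form: `E = sum(F g) / sum(g^2)` with `g` the model
#' evaluated at E = 1 kPa (through the origin; the correction targets the
#' shallow, contact-anchored window).
#'
#' @param ind an [to_indentation()] curve.
#' @param window depth window `(lo, hi]` in nm.
#' @param R tip radius in nm.
#' @param h layer thickness in nm.
#' @return List of class `hertz_fit` (same shape as [hertz_slope_fit()]).
#' @export
bottom_effect_fit <- function(ind, window, R, h) {
  w <- window_samples(ind, window)
  if (w$n < 8L)
    stop("bottom_effect_fit: fewer than 8 samples in the window", call. = FALSE)
  g <- bottom_effect_force(1, R, w$delta, h)
  E <- sum(w$force * g) / sum(g * g)
  rms <- sqrt(mean((w$force - E * g)^2))
  if (!is.finite(E) || E <= 0)
    return(structure(list(E = NA_real_, slope = NA_real_, rms = rms, n = w$n,
                          window = window, converged = FALSE,
                          method = "bottom_effect"), class = "hertz_fit"))
  structure(list(E = E, slope = E, rms = rms, n = w$n, window = window,
                 converged = TRUE, method = "bottom_effect"),
            class = "hertz_fit")
}

#' @export
print.hertz_fit <- function(x, ...) {
  cat(sprintf("Hertz fit (%s): E = %s kPa, rms = %.2f pN, n = %d, window (%g, %g] nm\n",
              x$method,
              if (is.na(x$E)) "NA (fit failed)" else sprintf("%.3g", x$E),
              x$rms, x$n, x$window[1L], x$window[2L]))
  invisible(x)
}

#' Depth-segmented elasticity: plasma membrane and cortex moduli
#'
#' Vertical segmentation of an indentation curve: the plasma-membrane (PM)
#' modulus from the shallow window (0, `pm_window_nm`] nm and the cortex
#' modulus from (`cortex_window_nm[1]`, `cortex_window_nm[2]`] nm. The cortex
#' value is absent when the curve never exceeds the PM window.
#'
#' Two fitting strategies are available. `method = "joint"` (the default)
#' fits the force-continuous two-layer contact model over the full depth
#' range at once,
#' `F = C_pm * min(delta, B)^(3/2) + C_cx * max(delta^(3/2) - B^(3/2), 0)`
#' with `B = pm_window_nm`, by nonnegative least squares (contact-anchored:
#' no intercept). Because samples just past the window boundary are explained
#' by the cortex term, a few nanometres of contact-point error cannot leak the
#' much stiffer cortex response into the membrane modulus - with independent
#' per-window fits that leakage is one-sided and inflates E_pm.
#' `method = "window"` fits each window separately with [hertz_slope_fit()]
#' (through-origin for the PM window, free intercept for the cortex window).
#' Both recover the true moduli exactly on noise-free two-layer data.
#'
#' When `config$bottom_effect` is set the membrane term uses the
#' finite-thickness corrected model with `layer_thickness_nm` (both methods).
#'
#' @param ind an [to_indentation()] curve.
#' @param R tip radius in nm.
#' @param nu Poisson ratio.
#' @param config an [fv_config()] (windows, bottom-effect settings, method).
#' @return Object of class `mechanics_fit`: `E_pm`, `E_cortex` (kPa, `NA`
#'   when absent or failed), `pm_window`, `cortex_window`, `rms_pm`,
#'   `rms_cortex` (pN), `bottom_effect_used`, `layer_thickness`, `n_pm`,
#'   `n_cortex`.
#' @export
segmented_moduli <- function(ind, R, nu = 0.5, config = fv_config()) {
  config <- as_fv_config(config)
  pm_w <- c(0, config$pm_window_nm)
  cx_w <- config$cortex_window_nm
  dmax <- if (length(ind$delta)) max(ind$delta) else 0
  if (identical(config$segment_method, "joint"))
    return(two_layer_joint_fit(ind, R, nu, config))
  fit_or_na <- function(expr) tryCatch(expr, error = function(e) NULL)
  pm <- fit_or_na(
    if (isTRUE(config$bottom_effect))
      bottom_effect_fit(ind, pm_w, R, config$layer_thickness_nm)
    else hertz_slope_fit(ind, pm_w, R, nu, intercept = FALSE)
  )
  cx <- if (dmax > cx_w[1L])
    fit_or_na(hertz_slope_fit(ind, cx_w, R, nu, intercept = TRUE))
  else NULL
  structure(list(
    E_pm = if (is.null(pm)) NA_real_ else pm$E,
    E_cortex = if (is.null(cx)) NA_real_ else cx$E,
    pm_window = pm_w, cortex_window = cx_w,
    rms_pm = if (is.null(pm)) NA_real_ else pm$rms,
    rms_cortex = if (is.null(cx)) NA_real_ else cx$rms,
    n_pm = if (is.null(pm)) 0L else pm$n,
    n_cortex = if (is.null(cx)) 0L else cx$n,
    bottom_effect_used = isTRUE(config$bottom_effect),
    layer_thickness = config$layer_thickness_nm,
    delta_max = dmax
  ), class = "mechanics_fit")
}

# force-continuous two-layer fit over (0, cortex top]; nonnegative LS in the
# two layer prefactors, contact-anchored (no intercept)
two_layer_joint_fit <- function(ind, R, nu, config) {
  bnd <- config$pm_window_nm
  top <- config$cortex_window_nm[2L]
  dmax <- if (length(ind$delta)) max(ind$delta) else 0
  sel <- ind$delta > 0 & ind$delta <= top
  d <- ind$delta[sel]; y <- ind$force[sel]
  n_pm <- sum(d <= bnd); n_cx <- sum(d > bnd)
  out <- list(E_pm = NA_real_, E_cortex = NA_real_,
              pm_window = c(0, bnd), cortex_window = config$cortex_window_nm,
              rms_pm = NA_real_, rms_cortex = NA_real_,
              n_pm = n_pm, n_cortex = n_cx,
              bottom_effect_used = isTRUE(config$bottom_effect),
              layer_thickness = config$layer_thickness_nm,
              delta_max = dmax)
  class(out) <- "mechanics_fit"
  if (n_pm < 8L) return(out)
  unit_pm <- function(dd)
    if (isTRUE(config$bottom_effect))
      bottom_effect_force(1, R, dd, config$layer_thickness_nm)
    else hertz_force(1, R, dd, nu)
  a <- unit_pm(pmin(d, bnd))
  conv <- (3 / 4) * (1 - nu^2) / sqrt(R) * 1e3  # slope -> kPa
  if (n_cx >= 8L && dmax > bnd) {
    b <- pmax(d^1.5 - bnd^1.5, 0)
    saa <- sum(a * a); sbb <- sum(b * b); sab <- sum(a * b)
    say <- sum(a * y); sby <- sum(b * y)
    det <- saa * sbb - sab * sab
    c1 <- c2 <- 0
    if (det > 1e-12 * saa * sbb) {
      c1 <- (sbb * say - sab * sby) / det
      c2 <- (saa * sby - sab * say) / det
    }
    if (c1 < 0 || c2 < 0 || det <= 1e-12 * saa * sbb) {
      s1 <- if (say > 0) say^2 / saa else 0
      s2 <- if (sby > 0) sby^2 / sbb else 0
      if (s1 >= s2) { c1 <- max(say, 0) / saa; c2 <- 0 }
      else { c2 <- max(sby, 0) / sbb; c1 <- 0 }
    }
    fitted <- c1 * a + c2 * b
    r <- y - fitted
    if (c1 > 0) {
      out$E_pm <- c1  # E scale for the membrane term (unit basis is 1 kPa)
      out$rms_pm <- sqrt(mean(r[d <= bnd]^2))
    }
    if (c2 > 0) {
      out$E_cortex <- c2 * conv
      out$rms_cortex <- sqrt(mean(r[d > bnd]^2))
    }
  } else {
    c1 <- sum(a * y) / sum(a * a)
    if (is.finite(c1) && c1 > 0) {
      out$E_pm <- c1
      out$rms_pm <- sqrt(mean((y - c1 * a)^2))
    }
  }
  out
}

#' @export
print.mechanics_fit <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "absent" else sprintf("%.3g kPa", v)
  cat("Depth-segmented mechanics fit\n")
  cat(sprintf("  E_pm     (0, %g] nm : %s (rms %.2f pN, n=%d)%s\n",
              x$pm_window[2L], fmt(x$E_pm), x$rms_pm, x$n_pm,
              if (x$bottom_effect_used)
                sprintf(" [bottom effect, h=%g nm]", x$layer_thickness) else ""))
  cat(sprintf("  E_cortex (%g, %g] nm : %s", x$cortex_window[1L],
              x$cortex_window[2L], fmt(x$E_cortex)))
  if (!is.na(x$E_cortex)) cat(sprintf(" (rms %.2f pN, n=%d)", x$rms_cortex, x$n_cortex))
  cat(sprintf("\n  max depth reached: %.1f nm\n", x$delta_max))
  invisible(x)
}

#' @export
coef.mechanics_fit <- function(object, ...) {
  c(E_pm = object$E_pm, E_cortex = object$E_cortex)
}
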