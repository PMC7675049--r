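#' Acquisition parameters for a force-volume dataset
#'
#' Bundles the instrument calibration values attached to every curve of a map.
#' Defaults correspond to typical live-cell multiparametric FD-AFM imaging
#' with soft pre-calibrated cantilevers: spring constants of roughly
#' 0.08-0.14 N/m, 65 nm tip radius, imaging setpoints of 500-750 pN, and
#' ~100 nm pixels.
#'
#' @param spring_constant Cantilever spring constant k in N/m; must lie in
#'   (0, 10].
#' @param tip_radius Tip apex radius R in nm; must be positive.
#' @param poisson_ratio Sample Poisson ratio, in \[0, 0.5\]. Cells are treated
#'   as incompressible (0.5).
#' @param setpoint_force Imaging force setpoint in pN (approach turnaround).
#' @param pixel_size Lateral pixel size in nm.
#' @param temperature Bath temperature in K (sets kBT for WLC fits).
#' @return An object of class `acquisition_params`.
#' @examples
#' acq <- acquisition_params()
#' acq$spring_constant
#' @export
acquisition_params <- function(spring_constant = 0.1,
                               tip_radius = 65,
                               poisson_ratio = 0.5,
                               setpoint_force = 750,
                               pixel_size = 100,
                               temperature = 310) {
  x <- list(
    spring_constant = as.numeric(spring_constant),
    tip_radius = as.numeric(tip_radius),
    poisson_ratio = as.numeric(poisson_ratio),
    setpoint_force = as.numeric(setpoint_force),
    pixel_size = as.numeric(pixel_size),
    temperature = as.numeric(temperature)
  )
  class(x) <- "acquisition_params"
  validate_acquisition(x)
  x
}

validate_acquisition <- function(x) {
  stop_if <- function(cond, msg) if (cond) stop(msg, call. = FALSE)
  for (f in c("spring_constant", "tip_radius", "poisson_ratio",
              "setpoint_force", "pixel_size", "temperature")) {
    stop_if(is.null(x[[f]]) || !is.finite(x[[f]]),
            sprintf("acquisition_params: missing or non-finite field '%s'", f))
  }
  stop_if(x$spring_constant <= 0 || x$spring_constant > 10,
          "acquisition_params: spring_constant must be in (0, 10] N/m")
  stop_if(x$tip_radius <= 0, "acquisition_params: tip_radius must be > 0")
  stop_if(x$poisson_ratio < 0 || x$poisson_ratio > 0.5,
          "acquisition_params: poisson_ratio must be in [0, 0.5]")
  stop_if(x$pixel_size <= 0, "acquisition_params: pixel_size must be > 0")
  invisible(x)
}

#' @export
print.acquisition_params <- function(x, ...) {
  cat("AFM acquisition parameters\n")
  cat(sprintf("  spring constant: %.3g N/m\n", x$spring_constant))
  cat(sprintf("  tip radius:      %.3g nm\n", x$tip_radius))
  cat(sprintf("  Poisson ratio:   %.2f\n", x$poisson_ratio))
  cat(sprintf("  setpoint force:  %.3g pN\n", x$setpoint_force))
  cat(sprintf("  pixel size:      %.3g nm\n", x$pixel_size))
  cat(sprintf("  temperature:     %.1f K\n", x$temperature))
  invisible(x)
}

# spring constant in pN/nm from N/m (1 N/m == 1000 pN/nm ... careful: see below)
# 1 N/m = 1e12 pN / 1e9 nm = 1000 pN/nm. A 0.1 N/m lever deflects 5 nm at 500 pN:
# 500 pN / (0.1 * 1000 pN/nm) = 5 nm.
k_pn_per_nm <- function(k_n_per_m) 1000 * k_n_per_m

# Boltzmann constant in pN nm / K
.kB_pN_nm <- 1.380649e-2

#' Analysis configuration
#'
#' Collects every tunable of the pipeline with the defaults used throughout
#' the package. Values can be overridden by name.
#'
#' @param ... named overrides of the defaults listed below.
#' @return A list of class `fv_config`.
#'
#' @details Keys (units, default):
#' \describe{
#'   \item{off_contact_fraction}{fraction of samples farthest from the surface
#'     used for baseline and noise fits (0.3).}
#'   \item{baseline_extrapolate}{"hold" (default) or "full": how the fitted
#'     baseline polynomial is applied beyond the off-contact fit range.}
#'   \item{contact_min_snr}{a curve whose peak force is below this multiple of
#'     the noise SD is flagged no-contact and excluded (5).}
#'   \item{contact_segment}{segment used to locate the contact point
#'     ("approach"; the retraction adhesion tail would bias the scan).}
#'   \item{fit_segment}{segment the mechanics fits run on ("retract").}
#'   \item{pm_window_nm}{upper edge of the plasma-membrane indentation window
#'     (50); the window is (0, pm_window_nm].}
#'   \item{cortex_window_nm}{cortex indentation window (c(50, 200]).}
#'   \item{segment_method}{"joint" (default; force-continuous two-layer fit
#'     over the full depth range) or "window" (independent per-window slope
#'     fits); see [segmented_moduli()].}
#'   \item{bottom_effect}{logical; use the finite-thickness corrected contact
#'     model for the PM window (FALSE).}
#'   \item{layer_thickness_nm}{layer thickness h for the bottom-effect model
#'     (50).}
#'   \item{rupture_snr}{detection threshold for rupture candidates, in noise
#'     SDs on the smoothed retraction (3).}
#'   \item{rupture_smooth}{width of the detection statistic's average: 2 (the
#'     default) thresholds on pairwise sample means, larger odd values use a
#'     centered running mean.}
#'   \item{specific_min_force_pN, specific_min_distance_nm}{specificity gates
#'     (80 pN, 5 nm).}
#'   \item{cholesterol_min_force_pN, nonadhesive_max_force_pN}{stratification
#'     gates (100 pN, 30 pN).}
#'   \item{wlc_lp_init_nm}{persistence length start value for WLC fits (0.38,
#'     a PEG linker).}
#'   \item{wlc_lp_bounds_nm}{box for Lp (c(0.05, 2)).}
#'   \item{wlc_lc_bounds_nm}{acceptance range for the fitted contour length
#'     (c(5, 60): linker plus protein scale).}
#'   \item{wlc_min_samples}{minimum samples between baseline crossing and
#'     rupture (10).}
#'   \item{wlc_rms_factor}{acceptance: fit RMS must be below this multiple of
#'     the noise SD (2).}
#'   \item{connectivity}{pixel connectivity for domain labeling (8).}
#' }
#' @examples
#' cfg <- fv_config(pm_window_nm = 40)
#' cfg$pm_window_nm
#' @export
fv_config <- function(...) {
  cfg <- list(
    off_contact_fraction = 0.3,
    baseline_extrapolate = "hold",
    contact_min_snr = 5,
    contact_segment = "approach",
    fit_segment = "retract",
    pm_window_nm = 50,
    cortex_window_nm = c(50, 200),
    segment_method = "joint",
    bottom_effect = FALSE,
    layer_thickness_nm = 50,
    rupture_snr = 3,
    rupture_smooth = 2,
    specific_min_force_pN = 80,
    specific_min_distance_nm = 5,
    cholesterol_min_force_pN = 100,
    nonadhesive_max_force_pN = 30,
    wlc_lp_init_nm = 0.38,
    wlc_lp_bounds_nm = c(0.05, 2),
    wlc_lc_bounds_nm = c(5, 60),
    wlc_min_samples = 10,
    wlc_rms_factor = 2,
    connectivity = 8
  )
  over <- list(...)
  if (length(over)) {
    if (is.null(names(over)) || any(!nzchar(names(over))))
      stop("fv_config: overrides must be named", call. = FALSE)
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown))
      stop("fv_config: unknown key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    cfg[names(over)] <- over
  }
  if (cfg$off_contact_fraction <= 0 || cfg$off_contact_fraction > 0.9)
    stop("fv_config: off_contact_fraction must be in (0, 0.9]", call. = FALSE)
  if (!cfg$connectivity %in% c(4, 8))
    stop("fv_config: connectivity must be 4 or 8", call. = FALSE)
  class(cfg) <- "fv_config"
  cfg
}

as_fv_config <- function(config) {
  if (inherits(config, "fv_config")) return(config)
  if (is.null(config)) return(fv_config())
  do.call(fv_config, as.list(config))
}
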