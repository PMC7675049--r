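#' Construct a force curve
#'
#' One pixel's approach/retraction force-vs-piezo-displacement record. The
#' piezo coordinate `z` increases towards the sample, so the approach segment
#' has strictly increasing `z` and the retraction strictly decreasing `z`
#' (both are stored in time order). Forces are in pN, displacements in nm.
#'
#' @param approach,retract two-column structures (z, force); matrices or data
#'   frames with columns `z` and `force`.
#' @param row,col pixel coordinates (1-based) inside the parent map; `NA` for
#'   free-standing curves.
#' @param acq an [acquisition_params()] object.
#' @return An object of class `force_curve` with elements `approach`,
#'   `retract` (each a list with numeric `z`, `force`), `row`, `col`, `acq`.
#' @examples
#' z <- seq(0, 400, length.out = 64)
#' fc <- force_curve(cbind(z, 0), cbind(rev(z), 0))
#' @export
force_curve <- function(approach, retract, row = NA_integer_,
                        col = NA_integer_, acq = acquisition_params()) {
  seg <- function(m, name, dir) {
    m <- as.matrix(m)
    if (ncol(m) < 2L)
      stop(sprintf("force_curve: %s segment needs (z, force) columns", name),
           call. = FALSE)
    z <- as.numeric(m[, 1L]); f <- as.numeric(m[, 2L])
    if (length(z) < 32L)
      stop(sprintf("force_curve: %s segment must have >= 32 samples", name),
           call. = FALSE)
    dz <- diff(z)
    if (!all(is.finite(z)) || !(all(dz > 0) || all(dz < 0)))
      stop(sprintf("force_curve: %s z must be strictly monotone", name),
           call. = FALSE)
    if (dir > 0 && dz[1L] < 0) { z <- rev(z); f <- rev(f) }
    if (!all(is.finite(f)))
      stop(sprintf("force_curve: %s force must be finite", name),
           call. = FALSE)
    list(z = z, force = f)
  }
  validate_acquisition(acq)
  x <- list(approach = seg(approach, "approach", 0),
            retract = seg(retract, "retract", 0),
            row = as.integer(row), col = as.integer(col), acq = acq)
  class(x) <- "force_curve"
  x
}

#' @export
print.force_curve <- function(x, ...) {
  cat(sprintf(
    "Force curve (pixel %s,%s): approach %d samples [%.1f, %.1f] nm, retract %d samples\n",
    x$row, x$col, length(x$approach$z), min(x$approach$z), max(x$approach$z),
    length(x$retract$z)))
  invisible(x)
}

curve_segment <- function(curve, which = c("approach", "retract")) {
  which <- match.arg(which)
  curve[[which]]
}

#' Convert an in-contact force record to an indentation curve
#'
#' Applies the cantilever deflection correction: the sample indentation is the
#' piezo travel past contact minus the lever deflection,
#' `delta = (z - z0) - F/k`. Indentation is clipped at zero and the samples
#' are returned in order of nondecreasing depth.
#'
#' @param curve a [force_curve()].
#' @param z0 contact point in nm (piezo coordinate).
#' @param k spring constant in N/m; defaults to the curve's acquisition value.
#' @param segment which segment to transform ("retract" by default, matching
#'   the convention of fitting the contact region of the retraction curve).
#' @return An object of class `indentation_curve`: list with `delta` (nm,
#'   nondecreasing), `force` (pN), `z0`, `segment`.
#' @examples
#' # 500 pN at 55 nm past contact with a 0.1 N/m lever: 5 nm deflection,
#' # so the sample is indented by 50 nm.
#' z <- seq(0, 100, length.out = 64)
#' f <- numeric(64); f[64] <- 500
#' fc <- force_curve(cbind(z, f), cbind(rev(z), rev(f)))
#' ic <- to_indentation(fc, z0 = 45, k = 0.1)
#' max(ic$delta)  # 50
#' @export
to_indentation <- function(curve, z0, k = curve$acq$spring_constant,
                           segment = c("retract", "approach")) {
  segment <- match.arg(segment)
  if (!is.finite(k) || k <= 0)
    stop("to_indentation: spring constant k must be > 0", call. = FALSE)
  if (!is.finite(z0)) stop("to_indentation: z0 must be finite", call. = FALSE)
  s <- curve_segment(curve, segment)
  kp <- k_pn_per_nm(k)
  keep <- s$z >= z0
  z <- s$z[keep]; f <- s$force[keep]
  delta <- pmax(0, (z - z0) - f / kp)
  o <- order(delta)
  x <- list(delta = delta[o], force = f[o], z0 = z0, segment = segment)
  class(x) <- "indentation_curve"
  x
}

#' @export
print.indentation_curve <- function(x, ...) {
  cat(sprintf(
    "Indentation curve (%s segment): %d samples, depth up to %.1f nm, z0 = %.1f nm\n",
    x$segment, length(x$delta), if (length(x$delta)) max(x$delta) else NA,
    x$z0))
  invisible(x)
}
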