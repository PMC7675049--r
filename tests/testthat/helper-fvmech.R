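# shared fixtures, all generated in code

default_acq <- acquisition_params()

# pure elastic half-space curve: flat baseline then Hertz response, both
# segments mirrored; optional white noise
make_hertz_curve <- function(E = 10, R = 65, nu = 0.5, z0 = 100, k = 0.1,
                             n = 256, depth = 150, noise = 0, seed = NULL,
                             drift = c(0, 0, 0)) {
  acq <- acquisition_params(spring_constant = k, tip_radius = R,
                            poisson_ratio = nu)
  kp <- 1000 * k
  dd <- seq(0, depth, length.out = 512)
  fd <- hertz_force(E, R, dd, nu)
  zd <- z0 + dd + fd / kp
  z <- seq(0, max(zd), length.out = n)
  f <- numeric(n)
  f[z >= z0] <- approx(zd, fd, xout = z[z >= z0], rule = 2)$y
  f <- f + drift[1] + drift[2] * z + drift[3] * z^2
  if (noise > 0) {
    if (!is.null(seed)) set.seed(seed)
    fa <- f + rnorm(n, sd = noise)
    fr <- f + rnorm(n, sd = noise)
  } else {
    fa <- fr <- f
  }
  force_curve(cbind(z, fa), cbind(rev(z), rev(fr)), acq = acq)
}

# indentation curve straight from a force law, bypassing contact detection
make_indentation <- function(force_fun, dmax = 200, n = 256) {
  d <- seq(dmax / n, dmax, length.out = n)
  structure(list(delta = d, force = force_fun(d), z0 = 0,
                 segment = "retract"),
            class = "indentation_curve")
}

# a small simulated map helper
small_map <- function(rows = 4, cols = 4, seed = 1, ...) {
  sc <- build_scene(rows, cols, seed = seed, ...)
  simulate_map(sc, default_acq, seed = seed)
}
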