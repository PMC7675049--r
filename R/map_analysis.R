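#' Analyse a force-volume map
#'
#' The map-level fit: applies [fit_curve()] to every pixel and assembles the
#' multiparametric channels - `height` (contact point), `E_pm`, `E_cortex`
#' (kPa), `adhesion_force` (pN; the last, i.e. largest-distance, specific
#' rupture of the pixel, 0 where none), the `specific` mask, the `analyzed`
#' mask and the per-pixel stratum - plus one event table row per rupture
#' candidate. Pixels whose curve never exceeds `contact_min_snr` noise SDs are
#' excluded (absent, `NA`, in all derived channels).
#'
#' @param map a [fv_map()].
#' @param config an [fv_config()].
#' @return Object of class `fv_analysis` with elements `channels` (named list
#'   of `rows x cols` matrices), `strata` (character matrix), `events` (data
#'   frame: `row`, `col`, `rupture_force_pN`, `rupture_distance_nm`, `Lc_nm`,
#'   `Lp_nm`, `specific`), `noise_sigma` (matrix), `n_analyzed`, `acq`,
#'   `config`, `rows`, `cols`. Methods: `print`, `summary`, `plot`.
#' @seealso [binding_probability()], [domain_sizes()],
#'   [stratified_pm_elasticity()]
#' @export
analyze_map <- function(map, config = fv_config()) {
  config <- as_fv_config(config)
  rows <- map$rows; cols <- map$cols
  na_m <- matrix(NA_real_, rows, cols)
  channels <- list(height = na_m, E_pm = na_m, E_cortex = na_m,
                   adhesion_force = na_m,
                   specific = matrix(FALSE, rows, cols),
                   analyzed = matrix(FALSE, rows, cols))
  strata <- matrix(NA_character_, rows, cols)
  noise_sigma <- na_m
  ev_list <- vector("list", rows * cols)
  for (r in seq_len(rows)) {
    for (c in seq_len(cols)) {
      fc <- map_curve(map, r, c)
      if (is.null(fc)) next
      fit <- fit_curve(fc, config)
      noise_sigma[r, c] <- fit$noise$sigma
      if (fit$no_contact) next
      channels$analyzed[r, c] <- TRUE
      channels$height[r, c] <- fit$z0
      channels$E_pm[r, c] <- fit$mechanics$E_pm
      channels$E_cortex[r, c] <- fit$mechanics$E_cortex
      strata[r, c] <- fit$stratum
      if (length(fit$events)) {
        spec <- vapply(fit$events, function(e) isTRUE(e$specific), logical(1))
        channels$specific[r, c] <- any(spec)
        channels$adhesion_force[r, c] <-
          if (any(spec)) fit$events[[max(which(spec))]]$rupture_force else 0
        ev_list[[(r - 1L) * cols + c]] <- data.frame(
          row = r, col = c,
          rupture_force_pN = vapply(fit$events, `[[`, numeric(1), "rupture_force"),
          rupture_distance_nm = vapply(fit$events, `[[`, numeric(1), "rupture_distance"),
          Lc_nm = vapply(fit$events, function(e)
            if (is.null(e$wlc)) NA_real_ else e$wlc$Lc, numeric(1)),
          Lp_nm = vapply(fit$events, function(e)
            if (is.null(e$wlc)) NA_real_ else e$wlc$Lp, numeric(1)),
          specific = spec)
      } else {
        channels$adhesion_force[r, c] <- 0
      }
    }
  }
  keep <- !vapply(ev_list, is.null, logical(1))
  events <- if (any(keep)) do.call(rbind, ev_list[keep])
  else data.frame(row = integer(), col = integer(),
                  rupture_force_pN = numeric(),
                  rupture_distance_nm = numeric(), Lc_nm = numeric(),
                  Lp_nm = numeric(), specific = logical())
  rownames(events) <- NULL
  structure(list(channels = channels, strata = strata, events = events,
                 noise_sigma = noise_sigma,
                 n_analyzed = sum(channels$analyzed),
                 acq = map$acq, config = config, rows = rows, cols = cols,
                 truth = map$truth),
            class = "fv_analysis")
}

#' Binding probability of a map
#'
#' Percentage of analysed pixels carrying a specific unbinding event:
#' `100 * n_specific / n_analyzed`. Excluded pixels are not in the
#' denominator.
#'
#' @param x an [analyze_map()] result, or a logical specific mask (in which
#'   case `analyzed` gives the denominator mask, default all).
#' @param analyzed optional logical matrix of analysed pixels.
#' @return Percentage in \[0, 100\]; `NA` (with a warning) when no pixel was
#'   analysed.
#' @export
binding_probability <- function(x, analyzed = NULL) {
  if (inherits(x, "fv_analysis")) {
    mask <- x$channels$specific
    analyzed <- x$channels$analyzed
  } else {
    mask <- x
    if (is.null(analyzed)) analyzed <- array(TRUE, dim(mask))
  }
  n <- sum(analyzed)
  if (n == 0L) {
    warning("binding_probability: no analysed pixels", call. = FALSE)
    return(NA_real_)
  }
  100 * sum(mask & analyzed) / n
}

#' Sizes of specific-event domains
#'
#' Labels the connected components of the specific mask and reports one row
#' per domain with its pixel count and physical area.
#'
#' @param x an [analyze_map()] result or a logical matrix.
#' @param connectivity 4 or 8 (default 8: irregular domains touching
#'   diagonally are one assembly).
#' @param pixel_size pixel edge in nm (taken from the analysis when
#'   available).
#' @return Object of class `domain_set`: data frame with `id`, `size_px`,
#'   `area_nm2`; attributes `labels` (integer matrix), `connectivity`,
#'   `pixel_size`.
#' @export
domain_sizes <- function(x, connectivity = NULL, pixel_size = NULL) {
  if (inherits(x, "fv_analysis")) {
    mask <- x$channels$specific
    if (is.null(connectivity)) connectivity <- x$config$connectivity
    if (is.null(pixel_size)) pixel_size <- x$acq$pixel_size
  } else {
    mask <- x
    if (is.null(connectivity)) connectivity <- 8
    if (is.null(pixel_size)) pixel_size <- 100
  }
  if (!connectivity %in% c(4, 8))
    stop("domain_sizes: connectivity must be 4 or 8", call. = FALSE)
  mask <- mask & !is.na(mask)
  lab <- cpp_label_components(as.logical(mask), nrow(mask), ncol(mask),
                              as.integer(connectivity))
  n <- attr(lab, "n_components")
  labm <- matrix(lab, nrow(mask), ncol(mask))
  sizes <- if (n > 0L) tabulate(lab[lab > 0L], nbins = n) else integer()
  out <- data.frame(id = seq_len(n), size_px = sizes,
                    area_nm2 = sizes * pixel_size^2)
  attr(out, "labels") <- labm
  attr(out, "connectivity") <- connectivity
  attr(out, "pixel_size") <- pixel_size
  class(out) <- c("domain_set", "data.frame")
  out
}

#' Plasma-membrane elasticity stratified by adhesion state
#'
#' Groups per-pixel PM moduli into the cholesterol-enriched stratum (pixels
#' with a specific rupture above the cholesterol force gate) and the
#' non-adhesive stratum (no candidate above the non-adhesive gate);
#' indeterminate pixels are excluded. When both strata are populated the two
#' groups are compared with a two-tailed Mann-Whitney U test.
#'
#' @param x an [analyze_map()] result.
#' @return List of class `stratified_elasticity`: `cholesterol`,
#'   `non_adhesive` (numeric vectors of E_pm, kPa), `test`
#'   ([mann_whitney_u()] result or `NULL`), `label`, `skipped` (flag: a
#'   stratum was empty).
#' @export
stratified_pm_elasticity <- function(x) {
  stopifnot(inherits(x, "fv_analysis"))
  e <- x$channels$E_pm
  chol <- e[x$strata == "cholesterol" & !is.na(x$strata) & !is.na(e)]
  nona <- e[x$strata == "non_adhesive" & !is.na(x$strata) & !is.na(e)]
  skipped <- length(chol) == 0L || length(nona) == 0L
  test <- if (!skipped) mann_whitney_u(chol, nona) else NULL
  structure(list(cholesterol = chol, non_adhesive = nona, test = test,
                 label = if (!skipped) significance_label(test$p) else NA_character_,
                 skipped = skipped),
            class = "stratified_elasticity")
}

#' @export
print.stratified_elasticity <- function(x, ...) {
  cat("PM elasticity by adhesion stratum\n")
  cat(sprintf("  cholesterol-enriched: n = %d, mean = %.3g kPa\n",
              length(x$cholesterol), mean(x$cholesterol)))
  cat(sprintf("  non-adhesive:         n = %d, mean = %.3g kPa\n",
              length(x$non_adhesive), mean(x$non_adhesive)))
  if (x$skipped) cat("  comparison skipped: empty stratum\n")
  else cat(sprintf("  Mann-Whitney U: p = %.4g (%s)\n", x$test$p, x$label))
  invisible(x)
}

#' Percentage decrease between two values
#'
#' `100 * (before - after) / before`, the convention used to report
#' softening after a treatment.
#'
#' @param before,after values on the same scale; `before` must be positive.
#' @return Percentage decrease (negative when `after > before`).
#' @examples
#' percent_change(37.5, 15.9)  # ~57.6
#' @export
percent_change <- function(before, after) {
  if (any(!is.finite(before)) || any(before <= 0))
    stop("percent_change: 'before' must be > 0", call. = FALSE)
  100 * (before - after) / before
}

#' Fold change
#'
#' @param a,b values on the same scale; `b` must be positive.
#' @return `a / b`.
#' @examples
#' fold_change(10.7, 5.3)
#' @export
fold_change <- function(a, b) {
  if (any(!is.finite(b)) || any(b <= 0))
    stop("fold_change: 'b' must be > 0", call. = FALSE)
  a / b
}

#' @export
print.fv_analysis <- function(x, ...) {
  cat(sprintf("Force-volume analysis %dx%d: %d/%d pixels analysed\n",
              x$rows, x$cols, x$n_analyzed, x$rows * x$cols))
  bp <- suppressWarnings(binding_probability(x))
  cat(sprintf("  binding probability: %.2f%%\n", bp))
  for (ch in c("E_pm", "E_cortex")) {
    v <- x$channels[[ch]]
    v <- v[is.finite(v)]
    if (length(v))
      cat(sprintf("  %-9s mean %.3g kPa (sd %.2g, n = %d)\n",
                  paste0(ch, ":"), mean(v), sd(v), length(v)))
  }
  cat(sprintf("  events: %d candidates, %d specific\n",
              nrow(x$events), sum(x$events$specific)))
  invisible(x)
}

#' @export
summary.fv_analysis <- function(object, ...) {
  ds <- domain_sizes(object)
  strat <- stratified_pm_elasticity(object)
  chan_stats <- lapply(object$channels[c("E_pm", "E_cortex", "adhesion_force")],
                       function(m) {
                         v <- m[is.finite(m)]
                         list(mean = mean(v), sd = sd(v), median = median(v),
                              n = length(v))
                       })
  spec_f <- object$events$rupture_force_pN[object$events$specific]
  out <- list(rows = object$rows, cols = object$cols,
              n_analyzed = object$n_analyzed,
              binding_probability = suppressWarnings(binding_probability(object)),
              channels = chan_stats,
              n_events = nrow(object$events),
              n_specific = sum(object$events$specific),
              specific_force_mean = if (length(spec_f)) mean(spec_f) else NA_real_,
              specific_force_sd = if (length(spec_f) > 1L) sd(spec_f) else NA_real_,
              domains = ds, stratified = strat,
              noise_median = median(object$noise_sigma, na.rm = TRUE))
  class(out) <- "summary.fv_analysis"
  out
}

#' @export
print.summary.fv_analysis <- function(x, ...) {
  cat(sprintf("Force-volume analysis summary (%dx%d, %d analysed pixels)\n",
              x$rows, x$cols, x$n_analyzed))
  cat(sprintf("  median noise:        %.2f pN\n", x$noise_median))
  cat(sprintf("  binding probability: %.2f%%\n", x$binding_probability))
  cat(sprintf("  specific events:     %d of %d candidates", x$n_specific,
              x$n_events))
  if (!is.na(x$specific_force_mean))
    cat(sprintf(" (force %.0f +/- %.0f pN)", x$specific_force_mean,
                if (is.na(x$specific_force_sd)) 0 else x$specific_force_sd))
  cat("\n")
  for (ch in names(x$channels)) {
    s <- x$channels[[ch]]
    if (s$n)
      cat(sprintf("  %-15s mean %.3g, sd %.2g, n = %d\n", paste0(ch, ":"),
                  s$mean, s$sd, s$n))
  }
  cat(sprintf("  domains: %d (sizes: %s px)\n", nrow(x$domains),
              if (nrow(x$domains)) paste(sort(x$domains$size_px,
                                              decreasing = TRUE)[
                                           seq_len(min(5, nrow(x$domains)))],
                                         collapse = ", ") else "-"))
  print(x$stratified)
  invisible(x)
}

#' @export
plot.fv_analysis <- function(x, channels = c("height", "E_pm", "E_cortex",
                                             "adhesion_force", "specific"),
                             ...) {
  channels <- intersect(channels, names(x$channels))
  op <- graphics::par(mfrow = grDevices::n2mfrow(length(channels)),
                      mar = c(2, 2, 2, 1))
  on.exit(graphics::par(op))
  for (ch in channels) {
    m <- x$channels[[ch]]
    storage.mode(m) <- "double"
    graphics::image(t(m[x$rows:1, , drop = FALSE]), axes = FALSE, main = ch,
                    col = grDevices::hcl.colors(64, "viridis"), ...)
  }
  invisible(x)
}
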