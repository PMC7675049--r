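#' Run the full analysis pipeline from a configuration
#'
#' Config-driven orchestration of simulate/read -> per-curve fits -> map
#' assembly -> map statistics. The configuration is a flat named list (or a
#' YAML file of one): either `input` (a container path, see [read_dataset()])
#' or `simulate` (a named list passed to [build_scene()]) selects the data
#' source; every [fv_config()] key is accepted as an analysis override; `seed`
#' drives all randomness; `out` (optional) names a JSON report file;
#' `export_dir` (optional) triggers [export_channels()].
#'
#' The report embeds the resolved configuration and package version, and
#' contains only quantities that are deterministic functions of the input
#' container and configuration, so a report can be regenerated exactly.
#'
#' @param config named list or path to a YAML file.
#' @return The report, invisibly (class `fv_report`), a nested list also
#'   written to `config$out` when given.
#' @examples
#' rep <- run_pipeline(list(simulate = list(rows = 4, cols = 4,
#'                                          coverage = 0, seed = 1),
#'                          seed = 1))
#' rep$results$binding_probability
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config))
      stop(sprintf("run_pipeline: config file not found: %s", config),
           call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config))
    stop("run_pipeline: config must be a named list or a YAML path",
         call. = FALSE)
  known_top <- c("input", "simulate", "acquisition", "seed", "out",
                 "export_dir", "n_samples")
  cfg_keys <- setdiff(names(config), known_top)
  unknown <- setdiff(cfg_keys, names(fv_config()))
  if (length(unknown))
    stop("run_pipeline: unknown config key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  an_cfg <- do.call(fv_config, config[cfg_keys])
  acq <- if (!is.null(config$acquisition))
    do.call(acquisition_params, config$acquisition) else acquisition_params()

  if (!is.null(config$input)) {
    if (!file.exists(config$input))
      stop(sprintf("run_pipeline: input container not found: %s",
                   config$input), call. = FALSE)
    map <- read_dataset(config$input)
    source <- list(type = "container", path = config$input)
  } else if (!is.null(config$simulate)) {
    sim <- config$simulate
    if (is.null(sim$seed)) sim$seed <- if (!is.null(config$seed)) config$seed
    else stop("run_pipeline: simulate needs a seed", call. = FALSE)
    scene <- do.call(build_scene, sim)
    map <- simulate_map(scene, acq,
                        n_samples = if (is.null(config$n_samples)) 512
                        else config$n_samples)
    source <- list(type = "simulated", seed = sim$seed)
  } else {
    stop("run_pipeline: config needs 'input' or 'simulate'", call. = FALSE)
  }

  an <- analyze_map(map, an_cfg)
  sm <- summary(an)
  results <- list(
    n_pixels = an$rows * an$cols,
    n_analyzed = an$n_analyzed,
    noise_median_pN = sm$noise_median,
    binding_probability = sm$binding_probability,
    n_events = sm$n_events,
    n_specific = sm$n_specific,
    specific_force_mean_pN = sm$specific_force_mean,
    specific_force_sd_pN = sm$specific_force_sd,
    channels = sm$channels,
    domain_sizes_px = sm$domains$size_px,
    strata = list(
      cholesterol = list(n = length(sm$stratified$cholesterol),
                         mean_E_pm_kPa = mean(sm$stratified$cholesterol)),
      non_adhesive = list(n = length(sm$stratified$non_adhesive),
                          mean_E_pm_kPa = mean(sm$stratified$non_adhesive)),
      mann_whitney_p = if (!sm$stratified$skipped) sm$stratified$test$p
      else NA_real_,
      label = sm$stratified$label,
      skipped = sm$stratified$skipped
    )
  )
  report <- list(package = "fvmech",
                 version = as.character(packageVersion("fvmech")),
                 source = source,
                 config = c(unclass(an_cfg),
                            list(seed = config$seed,
                                 acquisition = unclass(acq))),
                 results = results)
  class(report) <- c("fv_report", "list")
  if (!is.null(config$export_dir)) export_channels(an, config$export_dir)
  if (!is.null(config$out)) {
    dir.create(dirname(config$out), showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(unclass(report), config$out, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, null = "null")
  }
  invisible(report)
}

#' @export
print.fv_report <- function(x, ...) {
  cat(sprintf("fvmech pipeline report (v%s, %s input)\n", x$version,
              x$source$type))
  r <- x$results
  cat(sprintf("  %d/%d pixels analysed, noise %.1f pN\n", r$n_analyzed,
              r$n_pixels, r$noise_median_pN))
  cat(sprintf("  binding probability %.2f%%, %d specific of %d events\n",
              r$binding_probability, r$n_specific, r$n_events))
  invisible(x)
}
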