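#' Construct a force-volume map
#'
#' Grid container for per-pixel force curves plus derived channels. Pixels are
#' 1-based `(row, col)`, stored row-major (`index = (row - 1) * cols + col`).
#'
#' @param curves list of [force_curve()] objects, row-major, length
#'   `rows * cols`; `NULL` entries mark missing pixels.
#' @param rows,cols grid dimensions.
#' @param acq an [acquisition_params()] shared by the map.
#' @param channels named list of `rows x cols` matrices (derived maps:
#'   `height`, `E_pm`, `E_cortex`, `adhesion_force`, `specific`, ...).
#' @param truth optional generation ground truth (see [simulate_map()]).
#' @return Object of class `force_volume_map`.
#' @export
fv_map <- function(curves, rows, cols, acq = acquisition_params(),
                   channels = list(), truth = NULL) {
  if (length(curves) != rows * cols)
    stop("fv_map: need rows * cols curves (use NULL for missing pixels)",
         call. = FALSE)
  for (ch in names(channels)) {
    d <- dim(channels[[ch]])
    if (is.null(d) || d[1L] != rows || d[2L] != cols)
      stop(sprintf("fv_map: channel '%s' does not match the grid", ch),
           call. = FALSE)
  }
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 curves = curves, acq = acq, channels = channels,
                 truth = truth, format_version = 1L),
            class = "force_volume_map")
}

#' Retrieve one pixel's curve
#' @param map a [fv_map()].
#' @param row,col pixel coordinates (1-based).
#' @return The [force_curve()] at that pixel (or `NULL`).
#' @export
map_curve <- function(map, row, col) {
  map$curves[[(row - 1L) * map$cols + col]]
}

#' @export
print.force_volume_map <- function(x, ...) {
  n_ok <- sum(!vapply(x$curves, is.null, logical(1)))
  cat(sprintf("Force-volume map %dx%d (%d curves, %d channel%s%s)\n",
              x$rows, x$cols, n_ok, length(x$channels),
              if (length(x$channels) == 1L) "" else "s",
              if (!is.null(x$truth)) ", with ground truth" else ""))
  if (length(x$channels))
    cat("  channels:", paste(names(x$channels), collapse = ", "), "\n")
  invisible(x)
}

fv_schema_error <- function(field) {
  stop(structure(class = c("fv_schema_error", "error", "condition"),
                 list(message = sprintf(
                   "malformed force-volume container: missing or invalid field '%s'",
                   field), call = NULL)))
}

#' Write a force-volume dataset to a single-file container
#'
#' Serializes the map to one self-describing file with a fixed hierarchical
#' schema:
#' \preformatted{
#'   format        "fvd", format_version 1
#'   acquisition/  spring_constant, tip_radius, poisson_ratio,
#'                 setpoint_force, pixel_size, temperature
#'   grid/         rows, cols
#'   curves/       per pixel (row-major): approach and retract (z, force)
#'                 two-column matrices; NULL for missing pixels
#'   channels/     named rows x cols matrices of derived values
#'   truth/        generation ground truth, when present
#' }
#' The file is written uncompressed with a fixed field order, so two writes of
#' the same map are byte-identical.
#'
#' @param map a [fv_map()].
#' @param path output file path (conventionally `.fvd`).
#' @return `path`, invisibly.
#' @seealso [read_dataset()]
#' @export
write_dataset <- function(map, path) {
  if (!inherits(map, "force_volume_map"))
    stop("write_dataset: not a force_volume_map", call. = FALSE)
  obj <- list(
    format = "fvd",
    format_version = map$format_version,
    acquisition = unclass(map$acq),
    grid = list(rows = map$rows, cols = map$cols),
    curves = lapply(map$curves, function(fc) {
      if (is.null(fc)) return(NULL)
      list(approach = cbind(z = fc$approach$z, force = fc$approach$force),
           retract = cbind(z = fc$retract$z, force = fc$retract$force))
    }),
    channels = map$channels,
    truth = map$truth
  )
  saveRDS(obj, path, compress = FALSE)
  invisible(path)
}

#' Read a force-volume dataset container
#'
#' Inverse of [write_dataset()]; curves and metadata round-trip exactly.
#' Malformed containers raise an `fv_schema_error` naming the offending field.
#'
#' @param path container file written by [write_dataset()].
#' @return A [fv_map()].
#' @export
read_dataset <- function(path) {
  if (!file.exists(path))
    stop(sprintf("read_dataset: no such file: %s", path), call. = FALSE)
  obj <- tryCatch(readRDS(path), error = function(e) fv_schema_error("<file>"))
  if (!is.list(obj) || !identical(obj$format, "fvd")) fv_schema_error("format")
  if (is.null(obj$format_version)) fv_schema_error("format_version")
  if (is.null(obj$acquisition)) fv_schema_error("acquisition")
  for (f in c("spring_constant", "tip_radius", "poisson_ratio",
              "setpoint_force", "pixel_size", "temperature"))
    if (is.null(obj$acquisition[[f]])) fv_schema_error(paste0("acquisition/", f))
  if (is.null(obj$grid$rows) || is.null(obj$grid$cols)) fv_schema_error("grid")
  acq <- do.call(acquisition_params, obj$acquisition)
  rows <- obj$grid$rows; cols <- obj$grid$cols
  if (!is.list(obj$curves) || length(obj$curves) != rows * cols)
    fv_schema_error("curves")
  idx <- 0L
  curves <- lapply(obj$curves, function(cv) {
    idx <<- idx + 1L
    if (is.null(cv)) return(NULL)
    if (is.null(cv$approach) || is.null(cv$retract))
      fv_schema_error(sprintf("curves[%d]", idx))
    r <- ((idx - 1L) %/% cols) + 1L
    c <- ((idx - 1L) %% cols) + 1L
    force_curve(cv$approach, cv$retract, row = r, col = c, acq = acq)
  })
  fv_map(curves, rows, cols, acq,
         channels = if (is.null(obj$channels)) list() else obj$channels,
         truth = obj$truth)
}

#' Export derived channels and events
#'
#' Writes every computed channel both as a 32-bit float greyscale TIFF and as
#' a plain-text CSV grid, plus one CSV row per detected event. TIFF samples
#' are min-max scaled to \[0, 1\] (32-bit float TIFFs cannot portably store
#' arbitrary ranges); the affine transform is recorded in a sidecar
#' `<channel>_scale.txt` (two numbers: min max), and the CSV carries exact
#' values.
#'
#' @param x an [analyze_map()] result (`fv_analysis`) or a [fv_map()] with
#'   channels.
#' @param dir output directory (created if needed).
#' @param channels channel names to export; default all computed.
#' @return Named character vector of the files written, invisibly.
#' @export
export_channels <- function(x, dir, channels = NULL) {
  chans <- x$channels
  events <- if (inherits(x, "fv_analysis")) x$events else NULL
  if (is.null(channels)) channels <- names(chans)
  missing_ch <- setdiff(channels, names(chans))
  if (length(missing_ch))
    stop(sprintf("export_channels: channel not computed: %s",
                 paste(missing_ch, collapse = ", ")), call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- character()
  for (ch in channels) {
    m <- chans[[ch]]
    storage.mode(m) <- "double"
    csv <- file.path(dir, paste0(ch, ".csv"))
    write.table(m, csv, sep = ",", row.names = FALSE, col.names = FALSE,
                na = "NA")
    out[paste0(ch, "_csv")] <- csv
    tif <- file.path(dir, paste0(ch, ".tif"))
    mm <- m
    mm[!is.finite(mm)] <- NA
    lo <- suppressWarnings(min(mm, na.rm = TRUE))
    hi <- suppressWarnings(max(mm, na.rm = TRUE))
    if (!is.finite(lo)) { lo <- 0; hi <- 1 }
    scale <- if (hi > lo) hi - lo else 1
    mm <- (mm - lo) / scale
    mm[is.na(mm)] <- 0
    tiff::writeTIFF(mm, tif, bits.per.sample = 32L, reduce = FALSE)
    scl <- file.path(dir, paste0(ch, "_scale.txt"))
    writeLines(sprintf("%.17g %.17g", lo, hi), scl)
    out[paste0(ch, "_tif")] <- tif
    out[paste0(ch, "_scale")] <- scl
  }
  if (!is.null(events)) {
    ev_csv <- file.path(dir, "events.csv")
    ev <- events[, c("row", "col", "rupture_force_pN", "rupture_distance_nm",
                     "Lc_nm", "Lp_nm", "specific")]
    write.csv(ev, ev_csv, row.names = FALSE)
    out["events_csv"] <- ev_csv
  }
  invisible(out)
}

#' Re-import an exported channel CSV
#'
#' @param path a channel CSV written by [export_channels()].
#' @return A numeric matrix.
#' @export
import_channel_csv <- function(path) {
  m <- as.matrix(read.csv(path, header = FALSE))
  dimnames(m) <- NULL
  m
}
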