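#' @include AllClasses.R
NULL

.MSCAN_FIELDS <- c("samples_real", "samples_imag", "aline_interval_s")

#' Read and write MScan container files
#'
#' The scan container stores the complex samples as separate real and
#' imaginary matrices (`samples_real`, `samples_imag`, A-lines x depth)
#' together with the `aline_interval_s` attribute and optional
#' `lateral_positions`, using R native serialization. The round trip is
#' lossless (bit-identical samples). Files missing a required field raise a
#' schema error naming the field.
#'
#' @param path File path (conventionally `.mscan.rds`).
#' @param mscan An [MScan-class] (for writing).
#' @return `readMScan` returns an [MScan-class]; `writeMScan` returns
#'   `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".mscan.rds")
#' scan <- MScan(matrix(c(1 + 0i, 1i, -1 + 0i, -1i), 4, 1), 594e-9)
#' writeMScan(scan, f)
#' identical(samples(readMScan(f)), samples(scan))
#' @export
readMScan <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  obj <- readRDS(path)
  if (!is.list(obj) || !identical(obj$format, "mscan"))
    stop("not an MScan container: ", path)
  for (f in .MSCAN_FIELDS)
    if (is.null(obj[[f]]))
      stop(sprintf("MScan schema error: missing field '%s'", f))
  MScan(obj$samples_real + 1i * obj$samples_imag,
        obj$aline_interval_s,
        if (is.null(obj$lateral_positions)) numeric(0)
        else obj$lateral_positions)
}

#' @rdname readMScan
#' @export
writeMScan <- function(mscan, path) {
  stopifnot(is(mscan, "MScan"))
  saveRDS(list(format = "mscan", version = 1L,
               samples_real = Re(mscan@samples),
               samples_imag = Im(mscan@samples),
               aline_interval_s = mscan@aline_interval_s,
               lateral_positions = mscan@lateral_positions),
          path)
  invisible(path)
}

#' Tidy data.frame view of a velocity map
#'
#' @param x A [VelocityMap-class].
#' @param row.names,optional Ignored (S3 compatibility).
#' @param ... Ignored.
#' @return data.frame with `window_index`, `window_start_index`,
#'   `depth_index`, `axial_velocity_mps`.
#' @export
as.data.frame.VelocityMap <- function(x, row.names = NULL, optional = FALSE,
                                      ...) {
  V <- x@axial_velocity
  data.frame(
    window_index = rep(seq_len(nrow(V)), times = ncol(V)),
    window_start_index = rep(x@window_start_index, times = ncol(V)),
    depth_index = rep(seq_len(ncol(V)), each = nrow(V)),
    axial_velocity_mps = as.vector(V))
}

#' Export a velocity map as CSV
#'
#' One row per (window, depth) pixel with the signed axial velocity in m/s.
#'
#' @param map A [VelocityMap-class].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
writeVelocityCSV <- function(map, path) {
  stopifnot(is(map, "VelocityMap"))
  utils::write.csv(as.data.frame(map), path, row.names = FALSE)
  invisible(path)
}

## Signed diverging colormap (blue - white - red) with symmetric limits.
.divergingRGB <- function(V, limit = NULL) {
  if (is.null(limit)) limit <- max(abs(V), na.rm = TRUE)
  if (!is.finite(limit) || limit == 0) limit <- 1
  x <- pmax(pmin(V / limit, 1), -1)
  x[is.na(x)] <- 0
  r <- ifelse(x >= 0, 1, 1 + x)
  b <- ifelse(x <= 0, 1, 1 - x)
  g <- 1 - abs(x)
  array(c(r, g, b), dim = c(nrow(V), ncol(V), 3L))
}

#' Render a velocity map to a TIFF image
#'
#' Writes an RGB TIFF using a signed diverging colormap (blue for negative,
#' red for positive axial velocities) with symmetric limits, depth running
#' along image rows.
#'
#' @param map A [VelocityMap-class].
#' @param path Output TIFF path.
#' @param limit_mps Symmetric color limit (m/s); defaults to the largest
#'   absolute velocity in the map.
#' @return `path`, invisibly.
#' @export
writeVelocityTIFF <- function(map, path, limit_mps = NULL) {
  stopifnot(is(map, "VelocityMap"))
  rgb <- .divergingRGB(t(map@axial_velocity), limit = limit_mps)
  tiff::writeTIFF(rgb, path)
  invisible(path)
}

#' Write a run manifest
#'
#' Every command-line run emits one JSON manifest alongside its outputs
#' recording the command, its parameters, input/output paths, seed, tool
#' version and a timestamp, so any stochastic output is exactly
#' reproducible from its manifest.
#'
#' @param path Manifest path.
#' @param command Subcommand name.
#' @param params Named list of parameters (config snapshot).
#' @param inputs,outputs Character vectors of file paths.
#' @param seed Integer seed or `NA`.
#' @return `path`, invisibly.
#' @export
writeManifest <- function(path, command, params = list(),
                          inputs = character(0), outputs = character(0),
                          seed = NA_integer_) {
  manifest <- list(
    tool = "crDoppler",
    version = as.character(utils::packageVersion("crDoppler")),
    command = command,
    params = params,
    inputs = as.list(inputs),
    outputs = as.list(outputs),
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Serialize a detection report to JSON
#'
#' @param report A [DetectionReport-class].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
writeDetectionReportJSON <- function(report, path) {
  stopifnot(is(report, "DetectionReport"))
  obj <- list(
    estimator = report@estimator@kind,
    n_points = report@estimator@n_points,
    snr_condition = report@snr_condition,
    theoretical_floor_mps = report@theoretical_floor_mps,
    grid_minimum_mps = report@grid_minimum_mps,
    empirical_minimum_mps = report@empirical_minimum_mps,
    criterion = report@criterion)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
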