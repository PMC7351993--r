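# File I/O and run provenance: TIFF streams with affine scaling metadata,
# CSV tables, YAML/JSON run configuration with schema validation, and JSON
# run manifests with checksums.

.configError <- function(msg)
  stop(errorCondition(msg, class = c("srs_config_error", "error")))

.dataError <- function(msg)
  stop(errorCondition(msg, class = c("srs_data_error", "error")))

#' Write / read a simulated acquisition as portable files
#'
#' The stream is stored as a multi-page 32-bit TIFF (one page per color,
#' each page n_lines x n_lateral_pixels) rescaled to [0, 1]; the affine
#' (offset, scale) needed to invert the rescaling, together with the array
#' dimensions, lives in \code{stream_meta.json}. Line times, the FSC trace
#' and the ground truth are CSVs; droplet texture is serialized as a JSON
#' string column.
#'
#' @param acq list(stream, fsc) from \code{\link{renderStream}}.
#' @param truth the matching \linkS4class{GroundTruth}.
#' @param config the \linkS4class{AcquisitionConfig} used.
#' @param dir output directory (created if needed).
#' @return \code{writeAcquisition}: the directory, invisibly;
#'   \code{readAcquisition}: list(stream, fsc, truth, config).
#' @export
writeAcquisition <- function(acq, truth, config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  s <- acq$stream@samples
  rng <- range(s)
  offset <- rng[1]
  scale <- if (diff(rng) > 0) diff(rng) else 1
  pages <- lapply(seq_len(dim(s)[3]),
                  function(k) (s[, , k] - offset) / scale)
  tiff::writeTIFF(pages, file.path(dir, "stream.tif"),
                  bits.per.sample = 32L)
  jsonlite::write_json(
    list(offset = offset, scale = scale, dim = dim(s),
         config = .configAsList(config)),
    file.path(dir, "stream_meta.json"), auto_unbox = TRUE, digits = NA)
  write.csv(data.frame(line = seq_along(acq$stream@lineTimes) - 1L,
                       time_s = acq$stream@lineTimes),
            file.path(dir, "line_times.csv"), row.names = FALSE)
  write.csv(data.frame(time_s = acq$fsc@times, fsc = acq$fsc@values),
            file.path(dir, "fsc.csv"), row.names = FALSE)
  ev <- truth@events
  if (!is.null(ev$texture))
    ev$texture <- vapply(ev$texture, function(t)
      as.character(jsonlite::toJSON(t, digits = NA)), character(1))
  write.csv(ev, file.path(dir, "truth.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(rate = truth@rate, target_fraction = truth@targetFraction,
         duration = truth@duration),
    file.path(dir, "truth_meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname writeAcquisition
#' @export
readAcquisition <- function(dir) {
  metaPath <- file.path(dir, "stream_meta.json")
  if (!file.exists(metaPath)) .dataError(paste("no stream_meta.json in", dir))
  meta <- jsonlite::read_json(metaPath, simplifyVector = TRUE)
  pages <- tiff::readTIFF(file.path(dir, "stream.tif"), all = TRUE)
  d <- as.integer(meta$dim)
  if (length(pages) != d[3] || !all(dim(pages[[1]]) == d[1:2]))
    .dataError("stream.tif does not match the recorded dimensions")
  s <- array(0, d)
  for (k in seq_len(d[3]))
    s[, , k] <- pages[[k]] * meta$scale + meta$offset
  lt <- read.csv(file.path(dir, "line_times.csv"))
  fsc <- read.csv(file.path(dir, "fsc.csv"))
  ev <- read.csv(file.path(dir, "truth.csv"), stringsAsFactors = FALSE)
  if (!is.null(ev$texture))
    ev$texture <- lapply(ev$texture, function(x)
      as.data.frame(jsonlite::fromJSON(x)))
  tm <- jsonlite::read_json(file.path(dir, "truth_meta.json"),
                            simplifyVector = TRUE)
  cfg <- do.call(acquisitionConfig, as.list(meta$config))
  list(stream = new("LineScanStream", samples = s, lineTimes = lt$time_s),
       fsc = new("FSCTrace", values = fsc$fsc, times = fsc$time_s),
       truth = new("GroundTruth", events = ev, rate = tm$rate,
                   targetFraction = tm$target_fraction,
                   duration = tm$duration),
       config = cfg)
}

.configAsList <- function(config) {
  list(lineRate = config@lineRate, nLateralPixels = config@nLateralPixels,
       nColors = config@nColors, lateralFOV = config@lateralFOV,
       flowFOV = config@flowFOV, frameLines = config@frameLines,
       flowSpeed = config@flowSpeed, noiseSigma = config@noiseSigma,
       fscPulseWidth = config@fscPulseWidth,
       seed = if (length(config@seed) && !is.na(config@seed))
         config@seed else NULL)
}

#' Read and validate a run configuration
#'
#' YAML or JSON (by extension). Recognized blocks: \code{acquisition}
#' (fields of \code{\link{acquisitionConfig}}), \code{timing} (fields of
#' \code{\link{sortTimingConfig}}), \code{gate} (x_feature, y_feature,
#' vertices), \code{segmentation} (fields of
#' \code{\link{segmentationParams}}), plus \code{seed}, \code{duration} and
#' \code{output_dir}. Physically impossible values are rejected with
#' actionable messages before any computation.
#'
#' @param path config file path.
#' @return list(acquisition, timing, gate, segmentation, seed, duration,
#'   output_dir).
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) .configError(paste("config file not found:", path))
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  validateRunConfig(raw)
}

#' @rdname readRunConfig
#' @param config a raw config list (as parsed from YAML/JSON).
#' @export
validateRunConfig <- function(config) {
  acq <- tryCatch(do.call(acquisitionConfig, as.list(config$acquisition)),
                  error = function(e) .configError(paste(
                    "invalid acquisition block:", conditionMessage(e))))
  timing <- tryCatch(do.call(sortTimingConfig, as.list(config$timing)),
                     error = function(e) .configError(paste(
                       "invalid timing block:", conditionMessage(e))))
  if (!is.null(config$duration) && config$duration <= 0)
    .configError("duration must be > 0 seconds")
  if (!is.null(config$seed) &&
      (!is.numeric(config$seed) || config$seed != round(config$seed)))
    .configError("seed must be an integer")
  gate <- NULL
  if (!is.null(config$gate)) {
    g <- config$gate
    gate <- tryCatch(
      polygonGate(g$x_feature, g$y_feature,
                  matrix(unlist(g$vertices), ncol = 2, byrow = TRUE)),
      error = function(e) .configError(paste("invalid gate:",
                                             conditionMessage(e))))
  }
  seg <- tryCatch(do.call(segmentationParams,
                          as.list(config$segmentation)),
                  error = function(e) .configError(paste(
                    "invalid segmentation block:", conditionMessage(e))))
  list(acquisition = acq, timing = timing, gate = gate, segmentation = seg,
       seed = if (is.null(config$seed)) NULL else as.integer(config$seed),
       duration = config$duration, output_dir = config$output_dir)
}

#' Write a run manifest
#'
#' JSON with the software version, seed, echoed configuration, per-stage
#' event counts, status and MD5 checksums of the run's output files.
#' Run entry points write it on both success and failure (via on.exit).
#'
#' @param dir run directory.
#' @param seed seed used.
#' @param config configuration echo (any list).
#' @param counts named per-stage event counts.
#' @param files paths whose checksums to record.
#' @param status "success", "failure" or "running".
#' @return The manifest path, invisibly.
#' @export
writeManifest <- function(dir, seed, config = list(), counts = list(),
                          files = character(0), status = "success") {
  files <- files[file.exists(files)]
  manifest <- list(
    package = "SRSflowSort",
    version = as.character(packageVersion("SRSflowSort")),
    seed = seed, status = status, config = config, counts = counts,
    checksums = as.list(tools::md5sum(files)))
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
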