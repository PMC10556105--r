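#' @include dosePipeline.R
NULL

## ---------------------------------------------------------------------------
## TIFF input/output
## ---------------------------------------------------------------------------

#' Read a scanned film from TIFF
#'
#' Reads an 8- or 16-bit, 1- or 3-channel transmission scan. The pixel pitch
#' comes from the file's resolution metadata (dpi); when the file carries
#' none, `dpiFallback` is used with a warning. RGB images are reduced to one
#' channel (default red, the recommended channel for dose evaluation up to
#' 8 Gy).
#'
#' @param path TIFF file.
#' @param channel channel to extract from RGB input.
#' @param dpiFallback resolution to assume when the file has no metadata.
#' @return a [FilmScan-class] with intensities in counts.
#' @export
readFilmTIFF <- function(path, channel = c("red", "green", "blue", "gray"),
                         dpiFallback = NULL) {
  channel <- match.arg(channel)
  if (!file.exists(path)) stop("cannot read '", path, "'", call. = FALSE)
  img <- tiff::readTIFF(path, info = TRUE)
  bits <- attr(img, "bits.per.sample") %||% 8L
  dpi <- attr(img, "x.resolution")
  unit <- attr(img, "resolution.unit") %||% "inch"
  if (!is.null(dpi) && unit == "cm") dpi <- dpi * 2.54
  if (is.null(dpi) || !is.finite(dpi) || dpi <= 0) {
    if (is.null(dpiFallback))
      stop("'", path, "' carries no resolution metadata and no dpiFallback ",
           "was given", call. = FALSE)
    warning("no resolution metadata in '", basename(path),
            "'; assuming ", dpiFallback, " dpi", call. = FALSE)
    dpi <- dpiFallback
  }
  if (length(dim(img)) == 3L) {
    ch <- match(channel, c("red", "green", "blue"))
    if (is.na(ch))
      stop("channel 'gray' requested but the image has ", dim(img)[3],
           " channels", call. = FALSE)
    img <- img[, , ch]
  } else if (channel %in% c("red", "green", "blue")) {
    channel <- "gray"
  }
  # readTIFF returns intensities normalized to [0, 1]; restore integer counts
  counts <- round(img * (2^bits - 1))
  new("FilmScan", values = matrix(as.numeric(counts), nrow(img), ncol(img)),
      pixelPitch = dpiToPitch(dpi), origin = c(0, 0), channel = channel,
      bitDepth = as.integer(bits))
}

#' Write a film scan as TIFF
#'
#' @param scan a [FilmScan-class] or intensity matrix (counts).
#' @param path output path.
#' @param bitDepth bits per sample (8 or 16).
#' @return the path, invisibly.
#' @export
writeFilmTIFF <- function(scan, path, bitDepth = 16L) {
  v <- if (is(scan, "FilmGrid")) mapValues(scan) else as.matrix(scan)
  tiff::writeTIFF(v / (2^bitDepth - 1), path, bits.per.sample = bitDepth)
  invisible(path)
}

#' Export a map as 32-bit float TIFF
#'
#' The TIFF is stored normalized to [0, 1]; the scale factor (max absolute
#' value, at least 1) is returned and recorded in summaries so values are
#' recoverable exactly. Negative netOD noise is clamped to 0 in the export
#' (reporting time only; in-memory arithmetic is never clamped).
#'
#' @param map an [ODMap-class] or [DoseMap-class].
#' @param path output path.
#' @return the scale factor, invisibly.
#' @export
writeMapTIFF <- function(map, path) {
  stopifnot(is(map, "FilmGrid"))
  v <- mapValues(map)
  v[is.na(v)] <- 0
  v <- pmax(v, 0)
  scale <- max(1, max(v))
  tiff::writeTIFF(v / scale, path, bits.per.sample = 32L)
  invisible(scale)
}

mapSummary <- function(map, scale) {
  v <- mapValues(map)
  data.frame(n_rows = nrow(v), n_cols = ncol(v),
             pixel_pitch_mm = pixelPitch(map),
             min = min(v, na.rm = TRUE), max = max(v, na.rm = TRUE),
             mean = mean(v, na.rm = TRUE), sd = sd(as.vector(v), na.rm = TRUE),
             n_masked = sum(is.na(v)), tiff_scale = scale)
}

## ---------------------------------------------------------------------------
## Run configuration
## ---------------------------------------------------------------------------

.configKeys <- c("beam", "phantom", "response", "sensor", "film", "doses",
                 "nominal_dose", "seed", "outdir", "report_digits", "roi",
                 "calibration", "orientation", "mode")

#' Read and write run configurations
#'
#' Run configurations are YAML or JSON (chosen by extension) with a fixed
#' vocabulary of top-level keys; unknown keys are rejected so typos never
#' pass silently. Serialization round-trips losslessly.
#'
#' @param path file path (.yaml/.yml or .json).
#' @param config named list.
#' @return `readRunConfig`: the validated named list; `writeRunConfig`: the
#'   path, invisibly.
#' @name runconfig
#' @export
readRunConfig <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(cfg), .configKeys)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         "; allowed: ", paste(.configKeys, collapse = ", "), call. = FALSE)
  cfg
}

#' @rdname runconfig
#' @export
writeRunConfig <- function(config, path) {
  unknown <- setdiff(names(config), .configKeys)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::write_yaml(config, path)
  else jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                            pretty = TRUE)
  invisible(path)
}

## ---------------------------------------------------------------------------
## Results and manifest
## ---------------------------------------------------------------------------

#' Write analysis results with a reproducibility manifest
#'
#' Tables go to CSV, maps to 32-bit float TIFF plus a CSV summary (including
#' the TIFF scale factor), the configuration to JSON, and a manifest records
#' every file with its MD5 checksum, the configuration hash, the seed and
#' package/R versions -- enough to re-run the analysis exactly. An existing
#' manifest in `outdir` is never overwritten without `force`.
#'
#' @param tables named list of data.frames.
#' @param maps named list of [FilmGrid-class] maps.
#' @param outdir output directory (created if needed).
#' @param config named list describing the run.
#' @param seed the run's seed.
#' @param force overwrite an existing result set.
#' @return the manifest, invisibly.
#' @export
writeResults <- function(tables = list(), maps = list(), outdir,
                         config = list(), seed = NULL, force = FALSE) {
  manifestPath <- file.path(outdir, "manifest.json")
  if (file.exists(manifestPath) && !force)
    stop("'", outdir, "' already holds results; use force = TRUE to replace",
         call. = FALSE)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  cfgPath <- file.path(outdir, "config.json")
  jsonlite::write_json(config, cfgPath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files <- c(files, cfgPath)
  for (nm in names(tables)) {
    p <- file.path(outdir, paste0(nm, ".csv"))
    write.csv(tables[[nm]], p, row.names = FALSE, quote = FALSE)
    files <- c(files, p)
  }
  for (nm in names(maps)) {
    p <- file.path(outdir, paste0(nm, ".tif"))
    scale <- writeMapTIFF(maps[[nm]], p)
    ps <- file.path(outdir, paste0(nm, "_summary.csv"))
    write.csv(mapSummary(maps[[nm]], scale), ps, row.names = FALSE,
              quote = FALSE)
    files <- c(files, p, ps)
  }
  manifest <- list(
    files = setNames(as.list(unname(tools::md5sum(files))), basename(files)),
    config_hash = unname(tools::md5sum(cfgPath)),
    seed = seed,
    package = as.character(packageVersion("rcfdose")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}
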