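# File formats: multi-plane TIFF images with a plain-text metadata sidecar,
# tidy measurement CSV with a schema header, and YAML run configuration.
#
# TIFF planes are stored as 32-bit floats normalized to [0, 1]; the original
# intensity scale, pixel size, expansion factor, and channel names live in a
# YAML sidecar written next to the image (`<image>.meta.yaml`). A TIFF
# without a sidecar and without explicit calibration arguments is refused
# rather than silently defaulting.

sidecar_path <- function(path) paste0(path, ".meta.yaml")

#' Write an image and its calibration sidecar
#'
#' @param image an [image_plane()].
#' @param path output TIFF path; the sidecar goes to `<path>.meta.yaml`.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "image_plane"))
  scale <- max(1e-12, max(vapply(image$channels, max, 1.0)))
  planes <- lapply(image$channels, function(ch) pmax(ch, 0) / scale)
  tiff::writeTIFF(planes, path, bits.per.sample = 32L, reduce = FALSE)
  yaml::write_yaml(list(pixel_size_nm = image$pixel_size_nm,
                        expansion_factor = image$expansion_factor,
                        channels = names(image$channels),
                        intensity_scale = scale,
                        provenance = image$provenance),
                   sidecar_path(path))
  invisible(path)
}

#' Read an image with physical calibration
#'
#' Reads a multi-plane TIFF and its metadata sidecar. Explicit arguments
#' override the sidecar; a missing pixel size (no sidecar, no override) is an
#' error, never a silent default.
#'
#' @param path TIFF path.
#' @param pixel_size_nm optional override, expanded-space nm.
#' @param expansion_factor optional override.
#' @return an [image_plane()].
#' @export
read_image <- function(path, pixel_size_nm = NULL, expansion_factor = NULL) {
  if (!file.exists(path))
    stop_uexm(sprintf("no such file: %s", path), "uexm_io_error")
  planes <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(planes)) planes <- list(planes)
  meta <- if (file.exists(sidecar_path(path)))
    yaml::read_yaml(sidecar_path(path)) else list()
  px <- pixel_size_nm %||% meta$pixel_size_nm
  ef <- expansion_factor %||% meta$expansion_factor
  if (is.null(px))
    stop_uexm("pixel size unknown: no metadata sidecar and no override",
              "uexm_io_error")
  if (is.null(ef))
    stop_uexm("expansion factor unknown: no metadata sidecar and no override",
              "uexm_io_error")
  scale <- meta$intensity_scale %||% 1
  ch_names <- meta$channels %||% paste0("ch", seq_along(planes))
  channels <- lapply(planes, function(p) p * scale)
  names(channels) <- ch_names
  image_plane(channels, pixel_size_nm = px, expansion_factor = ef,
              provenance = meta$provenance %||% path)
}

MEASUREMENT_SCHEMA <- "# uexm measurement table v1"

#' Write a tidy measurement table
#'
#' CSV with a schema-version comment header and a deterministic column
#' order, so write -> read -> write is byte-identical.
#'
#' @param records data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(records, path) {
  records <- records[, sort(names(records)), drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(MEASUREMENT_SCHEMA, con)
  utils::write.table(records, con, sep = ",", row.names = FALSE,
                     col.names = TRUE, qmethod = "double")
  invisible(path)
}

#' Read a measurement table written by [write_measurements()]
#' @param path CSV path.
#' @return data frame.
#' @export
read_measurements <- function(path) {
  if (!file.exists(path))
    stop_uexm(sprintf("no such file: %s", path), "uexm_io_error")
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Load and validate a run configuration
#'
#' YAML configuration bundling the measurement constants: pixel size,
#' expansion factor (or punch/disk calibration inputs), profile subdivision
#' (default 3), half-maximum fraction (default 0.5), diameter mode, presence
#' threshold `k_sigma`, background method, and seed.
#'
#' @param path YAML file.
#' @return named list of validated settings, class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    stop_uexm(sprintf("no such file: %s", path), "uexm_io_error")
  cfg <- yaml::read_yaml(path)
  defaults <- list(subdivision = 3L, half_fraction = 0.5,
                   diameter_mode = "peak_to_peak", k_sigma = 3,
                   background = "annulus", seed = 1L)
  for (nm in names(defaults))
    cfg[[nm]] <- cfg[[nm]] %||% defaults[[nm]]
  if (is.null(cfg$expansion_factor)) {
    if (!is.null(cfg$measured_disk_mm))
      cfg$expansion_factor <- calibrate_expansion(
        cfg$measured_disk_mm, cfg$punch_diameter_mm %||% 4)$factor
    else
      stop_uexm("config needs expansion_factor or measured_disk_mm",
                "uexm_validation_error")
  }
  if (!is.null(cfg$pixel_size_nm)) assert_scalar_pos(cfg$pixel_size_nm,
                                                     "pixel_size_nm")
  assert_scalar_pos(cfg$expansion_factor, "expansion_factor")
  if (cfg$subdivision < 1) stop_uexm("subdivision must be >= 1",
                                     "uexm_validation_error")
  if (cfg$half_fraction <= 0 || cfg$half_fraction >= 1)
    stop_uexm("half_fraction must lie in (0, 1)", "uexm_validation_error")
  if (!cfg$diameter_mode %in% c("peak_to_peak", "outer_half_max"))
    stop_uexm("unknown diameter_mode", "uexm_validation_error")
  if (!cfg$background %in% c("annulus", "global_percentile"))
    stop_uexm("unknown background method", "uexm_validation_error")
  structure(cfg, class = "run_config")
}
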