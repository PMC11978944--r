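#' Write a map as 32-bit float TIFF with a JSON sidecar
#'
#' TIFF payloads are stored normalized to `[0, 1]`; the affine scale, the
#' NA fill value and any extra metadata go to a `<path>.json` sidecar so
#' that [read_map_tiff()] restores values and missingness exactly (to
#' 32-bit float precision).
#'
#' @param map numeric matrix (NA allowed).
#' @param path output `.tif` path.
#' @param meta named list of extra metadata for the sidecar.
#' @return `path`, invisibly.
#' @export
write_map_tiff <- function(map, path, meta = list()) {
  stopifnot(is.matrix(map))
  finite <- is.finite(map)
  lo <- if (any(finite)) min(map[finite]) else 0
  hi <- if (any(finite)) max(map[finite]) else 0
  scale <- if (hi > lo) hi - lo else 1
  norm <- (map - lo) / scale
  norm[!finite] <- 0
  suppressWarnings(tiff::writeTIFF(norm, path, bits.per.sample = 32L))
  sidecar <- c(list(format = "fusulm-map", dims = dim(map), offset = lo,
                    scale = scale, na_mask = which(!finite)), meta)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a map written by [write_map_tiff()]
#'
#' @param path `.tif` path with its `.json` sidecar alongside.
#' @return list with `map` (matrix, NA restored) and `meta` (sidecar list).
#' @export
read_map_tiff <- function(path) {
  sidecar_path <- paste0(path, ".json")
  if (!file.exists(sidecar_path))
    stop("missing JSON sidecar for map: ", sidecar_path)
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  if (is.null(meta$format) || meta$format != "fusulm-map")
    stop("malformed sidecar: missing or wrong 'format' field")
  m <- tiff::readTIFF(path)
  map <- m * meta$scale + meta$offset
  if (length(meta$na_mask)) map[meta$na_mask] <- NA_real_
  list(map = matrix(map, meta$dims[1], meta$dims[2]), meta = meta)
}

#' Write a complex frame stack as multi-page float TIFF
#'
#' Two pages per frame (real then imaginary part), jointly normalized; the
#' JSON sidecar records the affine scale, shape, frame rate and pixel size.
#'
#' @param stack a [frame_stack()].
#' @param path output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(stack, path) {
  stopifnot(inherits(stack, "frame_stack"))
  d <- dim(stack$frames)
  re <- Re(stack$frames); im <- Im(stack$frames)
  lo <- min(re, im); hi <- max(re, im)
  scale <- if (hi > lo) hi - lo else 1
  pages <- vector("list", 2 * d[3])
  for (k in seq_len(d[3])) {
    pages[[2 * k - 1]] <- (re[, , k] - lo) / scale
    pages[[2 * k]] <- (im[, , k] - lo) / scale
  }
  suppressWarnings(tiff::writeTIFF(pages, path, bits.per.sample = 32L))
  jsonlite::write_json(
    list(format = "fusulm-stack", dims = d, offset = lo, scale = scale,
         frame_rate_Hz = stack$frame_rate_Hz, pixel_um = stack$pixel_um,
         plane_id = stack$plane_id),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a frame stack written by [write_stack_tiff()]
#'
#' @param path `.tif` path with its `.json` sidecar alongside.
#' @return a [frame_stack()].
#' @export
read_stack_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (is.null(meta$format) || meta$format != "fusulm-stack")
    stop("malformed sidecar: missing or wrong 'format' field")
  pages <- tiff::readTIFF(path, all = TRUE)
  d <- meta$dims
  frames <- array(0 + 0i, dim = d)
  for (k in seq_len(d[3])) {
    frames[, , k] <- complex(
      real = pages[[2 * k - 1]] * meta$scale + meta$offset,
      imaginary = pages[[2 * k]] * meta$scale + meta$offset)
  }
  frame_stack(frames, meta$frame_rate_Hz, meta$pixel_um, meta$plane_id)
}

#' Write / read localization and track tables as CSV
#'
#' @param tab data.frame (e.g. from [localize_stack()] or [link_tracks()]).
#' @param path `.csv` path.
#' @return `path` invisibly (write); the data.frame (read).
#' @export
write_tracks_csv <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks_csv
#' @export
read_tracks_csv <- function(path) {
  utils::read.csv(path)
}

# allowed configuration schema: block -> field names
config_schema <- function() {
  list(
    seed = NULL, output = NULL,
    probe = c("n_arrays", "elements_per_array", "pitch_mm",
              "array_spacing_mm", "center_frequency_MHz",
              "slice_thickness_um"),
    motor_fus = c("acquisition_s", "move_s", "n_positions"),
    motor_ulm = c("acquisition_s", "move_s", "n_positions"),
    protocol = c("baseline_s", "on_s", "off_s", "n_repeats", "stim_rate_Hz"),
    acquisition = c("n_angles", "prf_Hz", "compounded_rate_Hz",
                    "mechanical_index", "max_tilt_deg"),
    phantom = c("n_per_level", "evoked_fraction", "extent_um"),
    fus = c("noise_sigma", "dt", "voxel_um"),
    ulm = c("duration_s", "mb_rate", "psf_sigma_um", "pixel_um",
            "clutter_rank", "clutter_amplitude", "noise_sigma",
            "detect_threshold", "window_px", "max_link_um",
            "max_gap_frames", "min_track_length", "grid_um",
            "speed_smooth_frames", "rank_cut", "frame_rate_Hz"),
    frc = c("criterion", "ring_width", "split_method"),
    glm = c("alpha", "hrf_alpha", "hrf_tau_s", "baseline"),
    group = c("n_acquisitions", "metric", "mask_mode"),
    ulm_total_s = NULL, n_steps = NULL)
}

#' Validate a pipeline configuration
#'
#' Checks the nested configuration list against the package schema; unknown
#' blocks or fields are rejected with an error naming the offending key.
#'
#' @param config nested named list.
#' @return `config`, invisibly, if valid.
#' @export
validate_config <- function(config) {
  schema <- config_schema()
  unknown <- setdiff(names(config), names(schema))
  if (length(unknown))
    stop("unknown configuration block(s): ", paste(unknown, collapse = ", "))
  for (blk in names(config)) {
    allowed <- schema[[blk]]
    if (is.null(allowed)) next
    bad <- setdiff(names(config[[blk]]), allowed)
    if (length(bad))
      stop("unknown field(s) in '", blk, "': ", paste(bad, collapse = ", "))
  }
  invisible(config)
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return validated configuration list.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  config <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else stop("unsupported config format: .", ext)
  validate_config(config)
  config
}
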