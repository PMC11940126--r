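# Serialization of volumes, phantom configs, and delimited tables.

VOLUME_FORMAT <- "cbiqus_scan_volume_v1"
ENVELOPE_FORMAT <- "cbiqus_envelope_v1"

grid_meta <- function(grid) {
  grid[c("extent_x", "extent_y", "step", "sampling_rate", "window_duration",
         "window_start_time")]
}

check_grid_shape <- function(arr, grid, what, path) {
  expected <- c(grid$n_x, grid$n_y, grid$n_t)
  if (!is.array(arr) || !identical(dim(arr), as.integer(expected))) {
    stop_cbi("'%s': %s shape does not match its grid metadata (%s expected).",
             path, what, paste(expected, collapse = " x "))
  }
}

#' Write / read a scan volume container
#'
#' Persists an RF volume as a single-file container holding the sample cube,
#' the grid metadata and a provenance string. Readers validate the format
#' tag and reject shape/metadata mismatches.
#'
#' @param vol A `qus_scan_volume`.
#' @param path File path.
#' @return `write_scan_volume()` returns `path` invisibly;
#'   `read_scan_volume()` returns the `qus_scan_volume`.
#' @export
write_scan_volume <- function(vol, path) {
  stopifnot(inherits(vol, "qus_scan_volume"))
  saveRDS(list(format = VOLUME_FORMAT, rf = vol$rf,
               grid = grid_meta(vol$grid), provenance = vol$provenance),
          path)
  invisible(path)
}

#' @rdname write_scan_volume
#' @export
read_scan_volume <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, VOLUME_FORMAT)) {
    stop_cbi("'%s' is not a scan-volume container.", path)
  }
  grid <- do.call(scan_grid, obj$grid)
  check_grid_shape(obj$rf, grid, "rf", path)
  if (!all(is.finite(obj$rf))) stop_cbi("'%s': non-finite RF samples.", path)
  structure(list(rf = obj$rf, grid = grid, provenance = obj$provenance),
            class = "qus_scan_volume")
}

#' Write / read an envelope volume container
#'
#' @param env A `qus_envelope`.
#' @param path File path.
#' @return `write_envelope_volume()` returns `path` invisibly;
#'   `read_envelope_volume()` the `qus_envelope`.
#' @export
write_envelope_volume <- function(env, path) {
  stopifnot(inherits(env, "qus_envelope"))
  saveRDS(list(format = ENVELOPE_FORMAT, env = env$env, env_db = env$env_db,
               grid = grid_meta(env$grid),
               reference_amplitude = env$reference_amplitude),
          path)
  invisible(path)
}

#' @rdname write_envelope_volume
#' @export
read_envelope_volume <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, ENVELOPE_FORMAT)) {
    stop_cbi("'%s' is not an envelope container.", path)
  }
  grid <- do.call(scan_grid, obj$grid)
  check_grid_shape(obj$env, grid, "env", path)
  check_grid_shape(obj$env_db, grid, "env_db", path)
  structure(list(env = obj$env, env_db = obj$env_db, grid = grid,
                 reference_amplitude = obj$reference_amplitude),
            class = "qus_envelope")
}

#' Write / read a phantom spec as a flat text config
#'
#' Scalar parameters are stored as YAML key-value pairs; a non-uniform
#' thickness map is stored inline as a list of rows. The CBI reflectivity
#' field is not stored: it is redrawn deterministically from `seed` at read
#' time, so a written-then-read spec regenerates the identical explant.
#'
#' @param spec A `qus_phantom`.
#' @param path File path (YAML text).
#' @return `write_phantom_config()` returns `path` invisibly;
#'   `read_phantom_config()` the rebuilt `qus_phantom`.
#' @export
write_phantom_config <- function(spec, path) {
  stopifnot(inherits(spec, "qus_phantom"))
  th <- spec$cartilage_thickness_map
  uniform <- length(unique(as.vector(th))) == 1L
  cfg <- list(
    format = "cbiqus_phantom_v1",
    grid = grid_meta(spec$grid),
    transducer = unclass(spec$transducer),
    explant_radius = spec$explant_radius,
    standoff_depth = spec$standoff_depth,
    tilt_x = spec$tilt_x, tilt_y = spec$tilt_y,
    cartilage_thickness = if (uniform) th[1, 1] else
      lapply(seq_len(nrow(th)), function(i) as.numeric(th[i, ])),
    cartilage_sound_speed = spec$cartilage_sound_speed,
    ac_reflectivity = spec$ac_reflectivity,
    cbi_reflectivity = spec$cbi_reflectivity,
    cbi_heterogeneity_db = spec$cbi_heterogeneity_db,
    cbi_heterogeneity_corr_length = spec$cbi_heterogeneity_corr_length,
    attenuation = spec$attenuation,
    noise_sigma = spec$noise_sigma,
    bone_scatter_depth = spec$bone_scatter_depth,
    bone_scatter_density = spec$bone_scatter_density,
    bone_scatter_amp = spec$bone_scatter_amp,
    bone_scatter_enabled = spec$bone_scatter_enabled,
    seed = spec$seed
  )
  yaml::write_yaml(cfg, path, precision = 17)
  invisible(path)
}

#' @rdname write_phantom_config
#' @export
read_phantom_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!identical(cfg$format, "cbiqus_phantom_v1")) {
    stop_cbi("'%s' is not a phantom config.", path)
  }
  th <- cfg$cartilage_thickness
  if (is.list(th)) th <- do.call(rbind, lapply(th, as.numeric))
  phantom_spec(
    grid = do.call(scan_grid, cfg$grid),
    transducer = do.call(transducer_spec, cfg$transducer),
    explant_radius = cfg$explant_radius,
    standoff_depth = cfg$standoff_depth,
    tilt_x = cfg$tilt_x, tilt_y = cfg$tilt_y,
    cartilage_thickness = th,
    cartilage_sound_speed = cfg$cartilage_sound_speed,
    ac_reflectivity = cfg$ac_reflectivity,
    cbi_reflectivity = cfg$cbi_reflectivity,
    cbi_heterogeneity_db = cfg$cbi_heterogeneity_db,
    cbi_heterogeneity_corr_length = cfg$cbi_heterogeneity_corr_length,
    attenuation = cfg$attenuation,
    noise_sigma = cfg$noise_sigma,
    bone_scatter_depth = cfg$bone_scatter_depth,
    bone_scatter_density = cfg$bone_scatter_density,
    bone_scatter_amp = cfg$bone_scatter_amp,
    bone_scatter_enabled = cfg$bone_scatter_enabled,
    seed = cfg$seed
  )
}

#' Export a peaks table as delimited text
#'
#' One row per grid position with times in microseconds and amplitudes in
#' millivolts: `ix, iy, ac_time_us, ac_amp_mV, cbi_time_us, cbi_amp_mV,
#' qc_pass, qc_reason`.
#'
#' @param peaks Tibble from [detect_volume_peaks()].
#' @param path Output path (TSV).
#' @return `path`, invisibly.
#' @export
export_peaks <- function(peaks, path) {
  out <- dplyr::transmute(
    peaks,
    ix = .data$ix, iy = .data$iy,
    ac_time_us = .data$ac_time * 1e6,
    ac_amp_mV = .data$ac_amp * 1e3,
    cbi_time_us = .data$cbi_time * 1e6,
    cbi_amp_mV = .data$cbi_amp * 1e3,
    qc_pass = .data$qc_pass, qc_reason = .data$qc_reason
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' Write an en face image as an 8-bit grayscale PNG
#'
#' QC-failed (`NA`) positions render as black. The normalized 0-1 scale is
#' recorded in a JSON sidecar next to the image.
#'
#' @param img A `qus_enface` (or any matrix of values in \[0, 1\]).
#' @param path Output path (`.png`).
#' @return `path`, invisibly.
#' @export
write_enface_png <- function(img, path) {
  m <- if (inherits(img, "qus_enface")) img$values else img
  m[is.na(m)] <- 0
  m <- pmin(pmax(m, 0), 1)
  # rotate so +y is up in the rendered image
  png::writePNG(t(m)[rev(seq_len(ncol(m))), , drop = FALSE], path)
  meta <- list(scale = "normalized 0-1",
               layer = if (inherits(img, "qus_enface")) img$layer else NA)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
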