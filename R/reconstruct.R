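# Image reconstruction: en face slabs, transverse slices, MIP.

#' Min-max normalize an envelope volume to \[0, 1\]
#'
#' Full-thickness signal intensity is rescaled linearly over the whole
#' volume so the minimum maps to 0 and the maximum to 1, prior to
#' segmentation.
#'
#' @param env A `qus_envelope`.
#' @return A `qus_norm_volume`: list with `values` (`n_x x n_y x n_t` in
#'   \[0, 1\]) and `grid`.
#' @export
normalize_full_thickness <- function(env) {
  stopifnot(inherits(env, "qus_envelope"))
  lo <- min(env$env)
  hi <- max(env$env)
  if (hi <= lo) stop_cbi("constant volume cannot be min-max normalized.")
  structure(
    list(values = (env$env - lo) / (hi - lo), grid = env$grid),
    class = "qus_norm_volume"
  )
}

#' En face segmented image of the AC surface or the CBI
#'
#' For each QC-passing scan position a depth slab is tied to the detected
#' peak: `[ac_time, ac_time + dt]` for the AC layer (200 um beyond the first
#' peak), `[cbi_time - dt, cbi_time + dt]` for the CBI (200 um above and
#' below the second peak), or the whole line for `layer = "full"`; `dt` is
#' the 200 um offset converted to round-trip time at the cartilage sound
#' speed (0.25 us). The pixel value is the maximum (default) or mean
#' normalized intensity inside the slab; QC-failed positions are `NA`.
#' Slabs reaching past the recorded window are clipped and counted in the
#' `"n_clipped"` attribute.
#'
#' @param norm_volume A `qus_norm_volume` from [normalize_full_thickness()].
#' @param peaks Tibble from [detect_volume_peaks()].
#' @param layer `"CBI"`, `"AC"`, or `"full"`.
#' @param slab_um Half-extent (CBI) / extent (AC) of the slab in um.
#' @param c_cartilage Cartilage sound speed for the um-to-time conversion.
#' @param agg Slab aggregation, `"max"` (default) or `"mean"`.
#' @return A `qus_enface`: list with `values` (`n_x x n_y`, \[0, 1\] or
#'   `NA`), `layer`, `slab_bounds_mm`, `grid`.
#' @export
enface_segment <- function(norm_volume, peaks, layer = c("CBI", "AC", "full"),
                           slab_um = 200, c_cartilage = 1600,
                           agg = c("max", "mean")) {
  stopifnot(inherits(norm_volume, "qus_norm_volume"))
  layer <- match.arg(layer)
  agg <- match.arg(agg)
  grid <- norm_volume$grid
  agg_fun <- if (agg == "max") max else mean
  dt <- 2 * slab_um * 1e-6 / c_cartilage
  vals <- matrix(NA_real_, grid$n_x, grid$n_y)
  n_clipped <- 0L
  ok <- peaks[peaks$qc_pass, , drop = FALSE]
  for (k in seq_len(nrow(ok))) {
    t0t1 <- switch(layer,
      AC = c(ok$ac_time[k], ok$ac_time[k] + dt),
      CBI = c(ok$cbi_time[k] - dt, ok$cbi_time[k] + dt),
      full = c(grid$window_start_time,
               grid$window_start_time + grid$window_duration)
    )
    i0 <- round(time_to_index(t0t1[1], grid))
    i1 <- round(time_to_index(t0t1[2], grid))
    if (i0 < 1L || i1 > grid$n_t) n_clipped <- n_clipped + 1L
    i0 <- max(i0, 1L)
    i1 <- min(i1, grid$n_t)
    vals[ok$ix[k], ok$iy[k]] <- agg_fun(norm_volume$values[ok$ix[k], ok$iy[k],
                                                           i0:i1])
  }
  structure(
    list(values = vals, layer = layer,
         slab_bounds_mm = c(below = slab_um / 1000, above = slab_um / 1000),
         grid = grid),
    class = "qus_enface",
    n_clipped = n_clipped
  )
}

#' Transverse (B-mode) slice through one scan row
#'
#' Extracts the dB image of row `iy` with a depth axis converted from time
#' of flight piecewise: coupling-bath sound speed above the detected AC
#' surface, cartilage sound speed below it. The AC boundary is the median
#' detected AC time of the QC-passing lines of that row (detected on the
#' spot when `peaks` is not supplied).
#'
#' @param env A `qus_envelope`.
#' @param iy Row index (1-based).
#' @param peaks Optional peaks tibble; detected for the row if missing.
#' @param c_coupling,c_cartilage Sound speeds, m/s.
#' @return A `qus_transverse`: list with `values` (`n_x x n_t`, dB),
#'   `depth_axis` (mm per time sample), `row_index`, `grid`.
#' @export
transverse_slice <- function(env, iy, peaks = NULL, c_coupling = 1500,
                             c_cartilage = 1600) {
  stopifnot(inherits(env, "qus_envelope"))
  grid <- env$grid
  if (length(iy) != 1L || iy < 1L || iy > grid$n_y) {
    stop_cbi("row index iy must lie in [1, %d].", grid$n_y)
  }
  iy <- as.integer(iy)
  if (is.null(peaks)) {
    rows <- lapply(seq_len(grid$n_x), function(ix) {
      detect_line_peaks(env$env[ix, iy, ], grid, ix = ix, iy = iy)
    })
    peaks <- dplyr::bind_rows(rows)
  }
  row_peaks <- peaks[peaks$iy == iy & peaks$qc_pass, , drop = FALSE]
  times <- grid_times(grid)
  if (nrow(row_peaks) > 0L) {
    t_ac <- stats::median(row_peaks$ac_time)
    depth <- ifelse(times <= t_ac,
                    c_coupling * times / 2,
                    c_coupling * t_ac / 2 + c_cartilage * (times - t_ac) / 2)
  } else {
    depth <- c_coupling * times / 2   # no detected surface: bath speed only
  }
  structure(
    list(values = env$env_db[, iy, ], depth_axis = depth * 1000,
         row_index = iy, grid = grid),
    class = "qus_transverse"
  )
}

#' Maximum intensity projection
#'
#' Element-wise maximum of a 3D volume along the depth, x, or y axis,
#' projecting the strongest backscatter onto a 2D plane.
#'
#' @param volume A 3D array, `qus_envelope` (its `env`), or
#'   `qus_norm_volume` (its `values`), indexed `x, y, t`.
#' @param axis `"depth"`, `"x"`, or `"y"`.
#' @return A `qus_mip`: list with `values` (2D matrix) and `axis`.
#' @export
mip_project <- function(volume, axis = c("depth", "x", "y")) {
  axis <- match.arg(axis)
  a <- if (inherits(volume, "qus_envelope")) volume$env
       else if (inherits(volume, "qus_norm_volume")) volume$values
       else volume
  if (!is.array(a) || length(dim(a)) != 3L) stop_cbi("need a 3D volume.")
  margin <- switch(axis, depth = c(1L, 2L), x = c(2L, 3L), y = c(1L, 3L))
  structure(list(values = apply(a, margin, max), axis = axis),
            class = "qus_mip")
}

raster_df <- function(values, xlab_vals, ylab_vals) {
  tibble(
    x = rep(xlab_vals, times = length(ylab_vals)),
    y = rep(ylab_vals, each = length(xlab_vals)),
    value = as.vector(values)
  )
}

#' @export
autoplot.qus_enface <- function(object, ...) {
  xy <- grid_coords(object$grid)
  df <- raster_df(object$values, xy$x, xy$y)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey85",
                                  name = "normalized\nintensity",
                                  limits = c(0, 1)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)",
                  title = sprintf("En face %s image", object$layer)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.qus_transverse <- function(object, ...) {
  xy <- grid_coords(object$grid)
  df <- raster_df(object$values, xy$x, object$depth_axis)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "dB") +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "x (mm)", y = "depth (mm)",
                  title = sprintf("Transverse slice, row %d",
                                  object$row_index)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.qus_mip <- function(object, ...) {
  d <- dim(object$values)
  df <- raster_df(object$values, seq_len(d[1]), seq_len(d[2]))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "intensity") +
    ggplot2::labs(title = sprintf("Maximum intensity projection (%s axis)",
                                  object$axis)) +
    ggplot2::theme_minimal()
}
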