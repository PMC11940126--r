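#' Transducer description
#'
#' Describes the focused single-element transducer used for pulse-echo
#' raster scanning. The default is a 35 MHz transducer with a -6 dB band of
#' roughly 27-43 MHz (fractional bandwidth 16/35), a 12.7 mm focal distance
#' and a 1500 m/s coupling (PBS) sound speed.
#'
#' @param center_frequency Pulse center frequency in Hz.
#' @param fractional_bandwidth -6 dB spectral band width as a fraction of the
#'   center frequency (strictly between 0 and 1).
#' @param focal_distance Focal distance in m.
#' @param depth_of_field Axial scale of the Gaussian focal sensitivity
#'   window, in m.
#' @param coupling_sound_speed Speed of sound in the coupling bath (m/s);
#'   must lie in \[1400, 1700\].
#' @return A `qus_transducer` list.
#' @export
#' @examples
#' transducer_spec()                       # 35 MHz default
#' transducer_spec(center_frequency = 15e6, focal_distance = 50.8e-3)
transducer_spec <- function(center_frequency = 35e6,
                            fractional_bandwidth = 16 / 35,
                            focal_distance = 12.7e-3,
                            depth_of_field = 2e-3,
                            coupling_sound_speed = 1500) {
  assert_scalar_num(center_frequency, "center_frequency", 0, strict_lower = TRUE)
  if (!is.numeric(fractional_bandwidth) || length(fractional_bandwidth) != 1L ||
      fractional_bandwidth <= 0 || fractional_bandwidth >= 1) {
    stop_cbi("`fractional_bandwidth` must lie strictly between 0 and 1.")
  }
  assert_scalar_num(focal_distance, "focal_distance", 0, strict_lower = TRUE)
  assert_scalar_num(depth_of_field, "depth_of_field", 0, strict_lower = TRUE)
  assert_scalar_num(coupling_sound_speed, "coupling_sound_speed", 1400, 1700)
  structure(
    list(
      center_frequency = center_frequency,
      fractional_bandwidth = fractional_bandwidth,
      focal_distance = focal_distance,
      depth_of_field = depth_of_field,
      coupling_sound_speed = coupling_sound_speed
    ),
    class = "qus_transducer"
  )
}

#' Raster-scan grid and time-base description
#'
#' The default matches a 6 mm x 6 mm raster with a 100 um step (61 x 61 scan
#' positions), digitized at 500 MHz over a 10 us window. `window_start_time`
#' is the round-trip time of flight of the first recorded sample.
#'
#' @param extent_x,extent_y Scanned extent in mm.
#' @param step Scan step in mm.
#' @param sampling_rate Digitizer rate in Hz.
#' @param window_duration Recorded window length in s.
#' @param window_start_time Round-trip time of flight of sample 1, in s.
#' @return A `qus_grid` list with derived counts `n_x`, `n_y`, `n_t`.
#' @export
scan_grid <- function(extent_x = 6, extent_y = 6, step = 0.1,
                      sampling_rate = 500e6, window_duration = 10e-6,
                      window_start_time = 12e-6) {
  assert_scalar_num(extent_x, "extent_x", 0, strict_lower = TRUE)
  assert_scalar_num(extent_y, "extent_y", 0, strict_lower = TRUE)
  assert_scalar_num(step, "step", 0, strict_lower = TRUE)
  assert_scalar_num(sampling_rate, "sampling_rate", 0, strict_lower = TRUE)
  assert_scalar_num(window_duration, "window_duration", 0, strict_lower = TRUE)
  assert_scalar_num(window_start_time, "window_start_time", 0)
  eps <- sqrt(.Machine$double.eps)
  n_x <- floor(extent_x / step + eps) + 1L
  n_y <- floor(extent_y / step + eps) + 1L
  n_t_exact <- sampling_rate * window_duration
  n_t <- round(n_t_exact)
  if (abs(n_t_exact - n_t) > 1e-6 || n_t < 2L) {
    stop_cbi("sampling_rate x window_duration must be an integer >= 2 (got %g).",
             n_t_exact)
  }
  structure(
    list(
      extent_x = extent_x, extent_y = extent_y, step = step,
      n_x = as.integer(n_x), n_y = as.integer(n_y),
      sampling_rate = sampling_rate,
      window_duration = window_duration,
      window_start_time = window_start_time,
      n_t = as.integer(n_t)
    ),
    class = "qus_grid"
  )
}

# Lateral scan coordinates in mm, centered on the grid.
grid_coords <- function(grid) {
  list(
    x = (seq_len(grid$n_x) - 1) * grid$step - grid$extent_x / 2,
    y = (seq_len(grid$n_y) - 1) * grid$step - grid$extent_y / 2
  )
}

# Sampled time base (round-trip TOF, s).
grid_times <- function(grid) {
  grid$window_start_time + (seq_len(grid$n_t) - 1) / grid$sampling_rate
}

# Circular explant mask (logical n_x x n_y).
explant_mask <- function(grid, radius) {
  xy <- grid_coords(grid)
  outer(xy$x^2, xy$y^2, `+`) <= radius^2
}

# Temporal std dev of the Gaussian pulse envelope realizing the -6 dB band.
pulse_sigma_t <- function(transducer) {
  half_width <- transducer$fractional_bandwidth * transducer$center_frequency / 2
  sigma_f <- half_width / sqrt(2 * log(db_to_amp(6)))
  1 / (2 * pi * sigma_f)
}

#' Sample the transmit pulse
#'
#' Builds the Gaussian-enveloped cosine pulse whose -6 dB spectral band spans
#' `fractional_bandwidth * center_frequency`, sampled at `sampling_rate` and
#' normalized to unit peak amplitude. The waveform is supported on about nine
#' envelope standard deviations centered on the peak.
#'
#' @param transducer A [transducer_spec()].
#' @param sampling_rate Sampling rate in Hz; must exceed four times the
#'   center frequency.
#' @return A tibble with columns `time` (s, 0 at the envelope peak) and
#'   `amplitude` (peak 1), carrying attributes `sigma_t` (envelope sd, s) and
#'   `center_frequency`.
#' @export
#' @examples
#' p <- make_pulse(transducer_spec(), 500e6)
#' max(abs(p$amplitude))  # 1
make_pulse <- function(transducer, sampling_rate) {
  stopifnot(inherits(transducer, "qus_transducer"))
  assert_scalar_num(sampling_rate, "sampling_rate", 0, strict_lower = TRUE)
  if (sampling_rate <= 4 * transducer$center_frequency) {
    stop_cbi(paste0("sampling_rate (%g Hz) must exceed 4x the center ",
                    "frequency (%g Hz) to sample the pulse adequately."),
             sampling_rate, transducer$center_frequency)
  }
  sigma_t <- pulse_sigma_t(transducer)
  h <- ceiling(4.5 * sigma_t * sampling_rate)
  t <- (-h:h) / sampling_rate
  amp <- exp(-t^2 / (2 * sigma_t^2)) *
    cos(2 * pi * transducer$center_frequency * t)
  out <- tibble(time = t, amplitude = amp)
  attr(out, "sigma_t") <- sigma_t
  attr(out, "center_frequency") <- transducer$center_frequency
  out
}

# Gaussian focal sensitivity at one-way depth z (m).
focal_weight <- function(z, transducer) {
  exp(-0.5 * ((z - transducer$focal_distance) / transducer$depth_of_field)^2)
}

# Separable Gaussian smoothing of a matrix with replicate-padding-free
# per-position kernel renormalization; sigma in pixels.
gaussian_smooth_matrix <- function(m, sigma) {
  if (sigma <= 0) return(m)
  h <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-h:h)^2) / (2 * sigma^2))
  smooth_vec <- function(v) {
    n <- length(v)
    num <- stats::convolve(c(rep(0, h), v, rep(0, h)), rev(k), type = "filter")
    den <- stats::convolve(c(rep(0, h), rep(1, n), rep(0, h)), rev(k),
                           type = "filter")
    num / den
  }
  n_r <- nrow(m)
  n_c <- ncol(m)
  if (n_r > 1L) m <- matrix(apply(m, 2L, smooth_vec), n_r, n_c)
  if (n_c > 1L) m <- t(matrix(apply(m, 1L, smooth_vec), n_c, n_r))
  m
}

# Spatially correlated log-normal reflectivity field with geometric mean
# `mean_v` and a log-sd equivalent to `heterogeneity_db` dB.
make_cbi_field <- function(grid, mean_v, heterogeneity_db, corr_length_mm,
                           seed) {
  sdlog <- heterogeneity_db * log(10) / 20
  withr::with_seed(seed, {
    g <- matrix(rnorm(grid$n_x * grid$n_y), grid$n_x, grid$n_y)
    g <- gaussian_smooth_matrix(g, corr_length_mm / grid$step)
    s <- stats::sd(as.vector(g))
    if (is.finite(s) && s > 0) g <- g / s
    mean_v * exp(sdlog * g)
  })
}

#' Phantom description with known ground truth
#'
#' Defines a synthetic osteochondral explant: a strong articular-surface
#' (AC) reflector at `standoff_depth` (optionally tilted), a laterally
#' heterogeneous mineral-front (CBI) reflector one cartilage thickness
#' deeper, optional sub-CBI bone scatterers, and additive Gaussian noise.
#' The CBI reflectivity field is drawn once at construction from `seed`, so
#' the same spec always describes the same explant; repeated calls to
#' [simulate_volume()] with different noise seeds model re-scans of that
#' explant.
#'
#' Defaults are anchored to the acquisition they emulate: a 3 mm diameter
#' explant centered in a 6 mm field, mean cartilage thickness 1.072 mm,
#' cartilage sound speed 1600 m/s, the CBI placed at the transducer focus,
#' and reflectivities chosen so the CBI echo sits near -10.5 dB below the
#' volume maximum after attenuation and focal weighting.
#'
#' @param grid A [scan_grid()].
#' @param transducer A [transducer_spec()].
#' @param explant_radius Explant radius in mm (no tissue echoes outside).
#' @param standoff_depth One-way water path to the articular surface at the
#'   explant center, in mm. Default places the CBI at the focal distance.
#' @param tilt_x,tilt_y Planar surface obliquity in mm depth per mm lateral.
#' @param cartilage_thickness Non-calcified cartilage thickness in mm: a
#'   scalar (uniform map) or an `n_x` x `n_y` matrix.
#' @param cartilage_sound_speed Speed of sound in cartilage, m/s.
#' @param ac_reflectivity AC echo reflectivity, V.
#' @param cbi_reflectivity Geometric-mean CBI reflectivity, V.
#' @param cbi_heterogeneity_db Marginal sd of the log-normal CBI field, dB.
#' @param cbi_heterogeneity_corr_length Lateral correlation length, mm.
#' @param attenuation One-way amplitude attenuation in cartilage, dB/mm.
#' @param noise_sigma Additive Gaussian noise sd, V.
#' @param bone_scatter_depth Depth extent of sub-CBI scatterers, mm.
#' @param bone_scatter_density Mean scatterer count per mm of depth.
#' @param bone_scatter_amp Scatterer reflectivity sd, V.
#' @param bone_scatter_enabled Logical; enabled by full decalcification.
#' @param seed Integer seed fixing the CBI reflectivity field (and the
#'   default noise stream of [simulate_volume()]).
#' @return A `qus_phantom` list; `$cbi_reflectivity_field` holds the drawn
#'   per-position reflectivity matrix and `$cartilage_thickness_map` the
#'   thickness map.
#' @export
phantom_spec <- function(grid = scan_grid(),
                         transducer = transducer_spec(),
                         explant_radius = 1.5,
                         standoff_depth = NULL,
                         tilt_x = 0, tilt_y = 0,
                         cartilage_thickness = 1.072,
                         cartilage_sound_speed = 1600,
                         ac_reflectivity = 1.0,
                         cbi_reflectivity = 0.331,
                         cbi_heterogeneity_db = 0.5,
                         cbi_heterogeneity_corr_length = 0.4,
                         attenuation = 1,
                         noise_sigma = 0.008,
                         bone_scatter_depth = 2,
                         bone_scatter_density = 5,
                         bone_scatter_amp = 0.03,
                         bone_scatter_enabled = FALSE,
                         seed = 1L) {
  stopifnot(inherits(grid, "qus_grid"), inherits(transducer, "qus_transducer"))
  assert_scalar_num(explant_radius, "explant_radius", 0, strict_lower = TRUE)
  if (is.matrix(cartilage_thickness)) {
    if (!all(dim(cartilage_thickness) == c(grid$n_x, grid$n_y))) {
      stop_cbi("cartilage_thickness matrix must be %d x %d.", grid$n_x, grid$n_y)
    }
    thickness_map <- cartilage_thickness
  } else {
    assert_scalar_num(cartilage_thickness, "cartilage_thickness", 0,
                      strict_lower = TRUE)
    thickness_map <- matrix(cartilage_thickness, grid$n_x, grid$n_y)
  }
  mask <- explant_mask(grid, explant_radius)
  if (any(thickness_map[mask] <= 0)) {
    stop_cbi("cartilage_thickness must be > 0 everywhere inside the explant.")
  }
  if (is.null(standoff_depth)) {
    standoff_depth <- transducer$focal_distance * 1000 -
      mean(thickness_map[mask])
  }
  assert_scalar_num(standoff_depth, "standoff_depth", 0, strict_lower = TRUE)
  assert_scalar_num(noise_sigma, "noise_sigma", 0)
  assert_scalar_num(attenuation, "attenuation", 0)
  assert_scalar_num(cartilage_sound_speed, "cartilage_sound_speed", 0,
                    strict_lower = TRUE)
  seed <- as.integer(seed)
  field <- make_cbi_field(grid, cbi_reflectivity, cbi_heterogeneity_db,
                          cbi_heterogeneity_corr_length, seed)
  structure(
    list(
      grid = grid, transducer = transducer,
      explant_radius = explant_radius,
      standoff_depth = standoff_depth,
      tilt_x = tilt_x, tilt_y = tilt_y,
      cartilage_thickness_map = thickness_map,
      cartilage_sound_speed = cartilage_sound_speed,
      ac_reflectivity = ac_reflectivity,
      cbi_reflectivity = cbi_reflectivity,
      cbi_heterogeneity_db = cbi_heterogeneity_db,
      cbi_heterogeneity_corr_length = cbi_heterogeneity_corr_length,
      cbi_reflectivity_field = field,
      attenuation = attenuation,
      noise_sigma = noise_sigma,
      bone_scatter_depth = bone_scatter_depth,
      bone_scatter_density = bone_scatter_density,
      bone_scatter_amp = bone_scatter_amp,
      bone_scatter_enabled = isTRUE(bone_scatter_enabled),
      seed = seed
    ),
    class = "qus_phantom"
  )
}

#' Simulate a raster-scan RF volume from a phantom
#'
#' For every in-mask scan position the RF line is the sum of an AC echo at
#' round-trip time `2 z_surface / c_coupling`, a CBI echo a further
#' `2 thickness / c_cartilage` later (attenuated by the round trip through
#' cartilage and weighted by the Gaussian focal sensitivity at its depth),
#' optional sub-CBI bone scatterers, and white Gaussian noise. Out-of-mask
#' positions contain noise only. Identical `(spec, seed)` give bit-identical
#' volumes.
#'
#' @param spec A [phantom_spec()].
#' @param seed Noise seed; defaults to `spec$seed`. Pass a different seed to
#'   model a re-scan of the same explant with fresh noise.
#' @return A `qus_scan_volume`: list with `rf` (`n_x x n_y x n_t` array, V),
#'   `grid`, and a `provenance` label.
#' @export
simulate_volume <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "qus_phantom"))
  grid <- spec$grid
  tr <- spec$transducer
  xy <- grid_coords(grid)
  times <- grid_times(grid)
  mask <- explant_mask(grid, spec$explant_radius)

  z_surf <- outer(xy$x * spec$tilt_x, xy$y * spec$tilt_y, `+`) +
    spec$standoff_depth                                   # mm, one-way
  th <- spec$cartilage_thickness_map                      # mm
  t_ac <- 2 * z_surf * 1e-3 / tr$coupling_sound_speed
  t_cbi <- t_ac + 2 * th * 1e-3 / spec$cartilage_sound_speed

  t_lo <- grid$window_start_time
  t_hi <- grid$window_start_time + grid$window_duration
  bad <- mask & (t_ac < t_lo | t_cbi >= t_hi)
  if (any(bad)) {
    ij <- which(bad, arr.ind = TRUE)[1, ]
    stop_cbi(paste0("echo arrival outside the recorded window at position ",
                    "(ix=%d, iy=%d): AC %.3f us, CBI %.3f us, window ",
                    "[%.3f, %.3f] us."),
             ij[1], ij[2], t_ac[ij[1], ij[2]] * 1e6, t_cbi[ij[1], ij[2]] * 1e6,
             t_lo * 1e6, t_hi * 1e6)
  }

  amp_ac <- spec$ac_reflectivity * focal_weight(z_surf * 1e-3, tr)
  amp_cbi <- spec$cbi_reflectivity_field *
    focal_weight((z_surf + th) * 1e-3, tr) *
    db_to_amp(-spec$attenuation * 2 * th)

  sigma_t <- pulse_sigma_t(tr)
  h <- ceiling(4.5 * sigma_t * grid$sampling_rate)
  fc <- tr$center_frequency
  n_t <- grid$n_t

  add_echo <- function(line, t0, amp) {
    i0 <- round((t0 - t_lo) * grid$sampling_rate) + 1
    idx <- max(1L, i0 - h):min(n_t, i0 + h)
    tau <- times[idx] - t0
    line[idx] <- line[idx] +
      amp * exp(-tau^2 / (2 * sigma_t^2)) * cos(2 * pi * fc * tau)
    line
  }

  rf <- array(0, dim = c(grid$n_x, grid$n_y, n_t))
  withr::with_seed(as.integer(seed), {
    for (iy in seq_len(grid$n_y)) {
      for (ix in seq_len(grid$n_x)) {
        line <- numeric(n_t)
        if (mask[ix, iy]) {
          line <- add_echo(line, t_ac[ix, iy], amp_ac[ix, iy])
          line <- add_echo(line, t_cbi[ix, iy], amp_cbi[ix, iy])
          if (spec$bone_scatter_enabled) {
            n_sc <- rpois(1, spec$bone_scatter_density * spec$bone_scatter_depth)
            if (n_sc > 0) {
              d <- runif(n_sc, 0, spec$bone_scatter_depth)    # mm below CBI
              a <- rnorm(n_sc, 0, spec$bone_scatter_amp) *
                focal_weight((z_surf[ix, iy] + th[ix, iy] + d) * 1e-3, tr) *
                db_to_amp(-spec$attenuation * 2 * (th[ix, iy] + d))
              t_sc <- t_cbi[ix, iy] + 2 * d * 1e-3 / spec$cartilage_sound_speed
              keep <- t_sc < t_hi
              for (j in which(keep)) {
                line <- add_echo(line, t_sc[j], a[j])
              }
            }
          }
        }
        if (spec$noise_sigma > 0) {
          line <- line + rnorm(n_t, 0, spec$noise_sigma)
        }
        rf[ix, iy, ] <- line
      }
    }
  })
  structure(
    list(
      rf = rf, grid = grid,
      provenance = sprintf(
        "phantom seed=%d noise_seed=%d fc=%.0fMHz standoff=%.3fmm",
        spec$seed, as.integer(seed), fc / 1e6, spec$standoff_depth)
    ),
    class = "qus_scan_volume"
  )
}

#' Surface-directed decalcification operator
#'
#' Mimics EDTA exposure: the mineral front recedes, so the apparent
#' cartilage thickness grows by `front_shift` everywhere in the explant.
#' `mode = "brief"` leaves the CBI reflectivity untouched; `mode = "full"`
#' additionally attenuates the CBI reflectivity field by `amplitude_drop`
#' decibels and enables sub-CBI bone scatterers (the demineralized zone no
#' longer shields the bone below). The input spec is not modified.
#'
#' @param spec A [phantom_spec()].
#' @param front_shift Mineral-front displacement in um (>= 0).
#' @param amplitude_drop CBI reflectivity drop in dB (>= 0; used only when
#'   `mode = "full"`).
#' @param mode `"brief"` or `"full"`.
#' @return A new `qus_phantom`.
#' @export
apply_decalcification <- function(spec, front_shift, amplitude_drop = 0,
                                  mode = c("brief", "full")) {
  stopifnot(inherits(spec, "qus_phantom"))
  mode <- match.arg(mode)
  assert_scalar_num(front_shift, "front_shift", 0)
  assert_scalar_num(amplitude_drop, "amplitude_drop", 0)
  out <- spec
  out$cartilage_thickness_map <- spec$cartilage_thickness_map +
    front_shift / 1000
  if (mode == "full") {
    out$cbi_reflectivity_field <- spec$cbi_reflectivity_field *
      db_to_amp(-amplitude_drop)
    out$bone_scatter_enabled <- TRUE
  }
  out
}

#' PBS swelling operator
#'
#' Long incubation in PBS swells unfixed cartilage: thickness grows by
#' `swell` micrometers with reflectivities unchanged.
#'
#' @param spec A [phantom_spec()].
#' @param swell Thickness increase in um (>= 0).
#' @return A new `qus_phantom`.
#' @export
apply_swelling <- function(spec, swell) {
  stopifnot(inherits(spec, "qus_phantom"))
  assert_scalar_num(swell, "swell", 0)
  spec$cartilage_thickness_map <- spec$cartilage_thickness_map + swell / 1000
  spec
}

#' @export
print.qus_scan_volume <- function(x, ...) {
  cat(sprintf("<qus_scan_volume> %d x %d positions x %d samples\n",
              x$grid$n_x, x$grid$n_y, x$grid$n_t))
  cat(sprintf("  window: %.2f-%.2f us at %.0f MHz sampling\n",
              x$grid$window_start_time * 1e6,
              (x$grid$window_start_time + x$grid$window_duration) * 1e6,
              x$grid$sampling_rate / 1e6))
  cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' @export
print.qus_phantom <- function(x, ...) {
  mask <- explant_mask(x$grid, x$explant_radius)
  cat(sprintf(
    "<qus_phantom> r=%.2f mm explant, standoff %.3f mm, thickness %.3f mm (mean)\n",
    x$explant_radius, x$standoff_depth, mean(x$cartilage_thickness_map[mask])))
  cat(sprintf("  AC %.3f V, CBI %.3f V (geo mean), noise %.1f mV, seed %d\n",
              x$ac_reflectivity, x$cbi_reflectivity, x$noise_sigma * 1000,
              x$seed))
  invisible(x)
}
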