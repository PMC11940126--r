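# Pulse synthesis, volume simulation, and the decalcification/swelling
# operators, checked against closed-form oracles on noise-free phantoms.

test_that("pulse realizes the requested -6 dB band and unit peak", {
  tr <- transducer_spec()   # 35 MHz, fractional bandwidth 16/35
  p <- make_pulse(tr, 500e6)
  expect_equal(max(abs(p$amplitude)), 1)
  expect_lt(abs(mean(p$amplitude)), 1e-3)

  n_pad <- 2^16
  spec_amp <- Mod(fft(c(p$amplitude, rep(0, n_pad - nrow(p)))))
  freqs <- (seq_len(n_pad) - 1) / n_pad * 500e6
  half <- freqs <= 250e6
  spec_amp <- spec_amp[half]
  freqs <- freqs[half]
  thresh <- max(spec_amp) * 10^(-6 / 20)
  band <- range(freqs[spec_amp >= thresh])
  expect_equal(band[1] / 1e6, 27, tolerance = 0.03)
  expect_equal(band[2] / 1e6, 43, tolerance = 0.03)
})

test_that("narrow-band limit concentrates the spectrum at 35 MHz", {
  tr <- transducer_spec(fractional_bandwidth = 0.02)
  p <- make_pulse(tr, 500e6)
  n_pad <- 2^18
  spec_amp <- Mod(fft(c(p$amplitude, rep(0, n_pad - nrow(p)))))
  freqs <- (seq_len(n_pad) - 1) / n_pad * 500e6
  peak_f <- freqs[freqs <= 250e6][which.max(spec_amp[freqs <= 250e6])]
  expect_equal(peak_f / 1e6, 35, tolerance = 1e-3)
})

test_that("pulse energy agrees between time and frequency domains", {
  p <- make_pulse(transducer_spec(), 500e6)
  x <- p$amplitude
  e_time <- sum(x^2)
  e_freq <- sum(Mod(fft(x))^2) / length(x)
  expect_equal(e_time, e_freq, tolerance = 1e-9)
})

test_that("undersampled pulse synthesis is rejected", {
  expect_error(make_pulse(transducer_spec(), 100e6), "4x the center")
})

test_that("forced geometry places the CBI echo 1.25 us after the AC echo", {
  # standoff at the focal distance, 1.000 mm cartilage at 1600 m/s
  grid <- scan_grid(extent_x = 0.01, extent_y = 0.01, step = 0.1,
                    window_duration = 4e-6, window_start_time = 16e-6)
  sp <- phantom_spec(grid = grid, explant_radius = 0.2, standoff_depth = 12.7,
                     cartilage_thickness = 1.0, noise_sigma = 0,
                     cbi_heterogeneity_db = 0)
  vol <- simulate_volume(sp)
  env <- compute_envelope(vol)
  pk <- detect_line_peaks(env$env[1, 1, ], grid)
  expect_true(pk$qc_pass)
  expect_equal(pk$cbi_time - pk$ac_time, 1.25e-6, tolerance = 2e-9 / 1.25e-6)
})

test_that("noise-free homogeneous phantom gives identical in-mask lines", {
  sp <- small_phantom(noise_sigma = 0, cbi_heterogeneity_db = 0)
  vol <- simulate_volume(sp)
  mask <- which(cbiqus:::explant_mask(sp$grid, sp$explant_radius),
                arr.ind = TRUE)
  ref_line <- vol$rf[mask[1, 1], mask[1, 2], ]
  for (k in seq_len(nrow(mask))) {
    expect_equal(vol$rf[mask[k, 1], mask[k, 2], ], ref_line)
  }
})

test_that("echo amplitudes follow the closed-form focal weight and attenuation", {
  sp <- small_phantom(noise_sigma = 0, cbi_heterogeneity_db = 0,
                      standoff_depth = 11.0, cartilage_thickness = 1.2)
  vol <- simulate_volume(sp)
  env <- compute_envelope(vol)
  pk <- detect_line_peaks(env$env[6, 6, ], sp$grid)
  fw <- function(z_mm) {
    exp(-0.5 * ((z_mm * 1e-3 - sp$transducer$focal_distance) /
                  sp$transducer$depth_of_field)^2)
  }
  expected_ratio <- (sp$ac_reflectivity * fw(11.0)) /
    (sp$cbi_reflectivity_field[6, 6] * fw(12.2) * 10^(-sp$attenuation * 2 * 1.2 / 20))
  expect_equal(pk$ac_amp / pk$cbi_amp, expected_ratio, tolerance = 0.01)
})

test_that("noise-free RF is linear in the reflectivities", {
  sp1 <- small_phantom(noise_sigma = 0)
  sp2 <- sp1
  sp2$ac_reflectivity <- 2 * sp1$ac_reflectivity
  sp2$cbi_reflectivity_field <- 2 * sp1$cbi_reflectivity_field
  v1 <- simulate_volume(sp1)
  v2 <- simulate_volume(sp2)
  expect_equal(v2$rf, 2 * v1$rf, tolerance = 1e-12)
})

test_that("out-of-mask lines carry only noise", {
  sp <- small_phantom(seed = 3)
  vol <- simulate_volume(sp)
  mask <- cbiqus:::explant_mask(sp$grid, sp$explant_radius)
  out_idx <- which(!mask, arr.ind = TRUE)
  for (k in seq_len(nrow(out_idx))) {
    expect_lte(max(abs(vol$rf[out_idx[k, 1], out_idx[k, 2], ])),
               6 * sp$noise_sigma)
  }
})

test_that("identical spec and seed give bit-identical volumes", {
  sp <- small_phantom(seed = 42, bone_scatter_enabled = TRUE)
  v1 <- simulate_volume(sp, seed = 7)
  v2 <- simulate_volume(sp, seed = 7)
  expect_identical(v1$rf, v2$rf)
  v3 <- simulate_volume(sp, seed = 8)
  expect_false(identical(v3$rf, v1$rf))
})

test_that("echo arrivals outside the window are rejected with the position", {
  grid <- small_grid(window = 1e-6, start = 14e-6)  # too short for the CBI
  expect_error(
    simulate_volume(phantom_spec(grid = grid, explant_radius = 0.5)),
    "outside the recorded window at position"
  )
})

test_that("spec invariants are enforced at construction", {
  expect_error(phantom_spec(cartilage_thickness = -1), "> 0")
  expect_error(transducer_spec(coupling_sound_speed = 300), "coupling_sound_speed")
  expect_error(transducer_spec(fractional_bandwidth = 1.2), "strictly between")
  expect_error(scan_grid(sampling_rate = 500e6, window_duration = 3.3e-9),
               "integer")
})

test_that("decalcification shifts the front and (full mode) dims the CBI", {
  sp <- small_phantom(cartilage_thickness = 1.0)
  brief <- apply_decalcification(sp, front_shift = 100, mode = "brief")
  expect_equal(brief$cartilage_thickness_map,
               matrix(1.1, sp$grid$n_x, sp$grid$n_y))
  expect_equal(brief$cbi_reflectivity_field, sp$cbi_reflectivity_field)
  expect_false(brief$bone_scatter_enabled)

  ident <- apply_decalcification(sp, 0, 0, "brief")
  expect_equal(ident, sp)

  full <- apply_decalcification(sp, 430, amplitude_drop = 6.63, mode = "full")
  expect_equal(full$cbi_reflectivity_field,
               sp$cbi_reflectivity_field * 10^(-6.63 / 20))
  expect_equal(full$cbi_reflectivity_field[1, 1] / sp$cbi_reflectivity_field[1, 1],
               0.466, tolerance = 0.001)
  expect_true(full$bone_scatter_enabled)
  # input spec untouched
  expect_equal(sp$cartilage_thickness_map[1, 1], 1.0)
  expect_error(apply_decalcification(sp, -5), ">=")
})

test_that("swelling is additive and composes", {
  sp <- small_phantom(cartilage_thickness = 1.0)
  expect_equal(apply_swelling(sp, 0), sp)
  expect_equal(apply_swelling(sp, 102)$cartilage_thickness_map[1, 1], 1.102)
  expect_equal(apply_swelling(apply_swelling(sp, 40), 62),
               apply_swelling(sp, 102))
  expect_equal(apply_swelling(sp, 102)$cbi_reflectivity_field,
               sp$cbi_reflectivity_field)
})
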