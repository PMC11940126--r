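# En face segmentation, transverse slices and MIP against ground truth and
# brute-force oracles.

fake_env <- function(arr, grid) {
  structure(list(env = arr, env_db = 20 * log10(pmax(arr, 1e-12) / max(arr)),
                 grid = grid, reference_amplitude = max(arr)),
            class = "qus_envelope")
}

test_that("min-max normalization maps the volume onto [0, 1] linearly", {
  grid <- small_grid()
  arr <- array(runif(11 * 11 * 2000, 0, 0.8), c(11, 11, 2000))
  arr[1, 1, 1] <- 0
  arr[2, 2, 2] <- 0.8
  arr[3, 3, 3] <- 0.4
  norm <- normalize_full_thickness(fake_env(arr, grid))
  expect_equal(min(norm$values), 0)
  expect_equal(max(norm$values), 1)
  expect_equal(norm$values[3, 3, 3], 0.5)
  const <- fake_env(array(0.3, c(11, 11, 2000)), grid)
  expect_error(normalize_full_thickness(const), "constant")
})

test_that("normalization and MIP commute (same monotone map)", {
  set.seed(77)
  grid <- small_grid()
  for (rep in 1:5) {
    arr <- array(runif(11 * 11 * 2000), c(11, 11, 2000))
    env <- fake_env(arr, grid)
    a <- mip_project(normalize_full_thickness(env), "depth")$values
    m <- mip_project(env, "depth")$values
    b <- (m - min(arr)) / (max(arr) - min(arr))
    expect_equal(a, b)
  }
})

test_that("MIP equals a brute-force loop maximum and is monotone", {
  set.seed(11)
  for (rep in 1:100) {
    v <- array(runif(5 * 5 * 7), c(5, 5, 7))
    m <- mip_project(v, "depth")$values
    for (i in 1:5) for (j in 1:5) {
      mx <- -Inf
      for (k in 1:7) if (v[i, j, k] > mx) mx <- v[i, j, k]
      expect_identical(m[i, j], mx)
    }
  }
  # single hot voxel
  v <- array(0, c(5, 5, 7))
  v[3, 4, 6] <- 2
  m <- mip_project(v, "depth")$values
  expect_equal(m[3, 4], 2)
  expect_equal(sum(m), 2)
  # max dominance over every constituent slice
  v <- array(runif(5 * 5 * 7), c(5, 5, 7))
  m <- mip_project(v, "depth")$values
  for (k in 1:7) expect_true(all(m >= v[, , k]))
  # monotone: raising one voxel never lowers any projected pixel
  v2 <- v
  v2[2, 2, 3] <- v[2, 2, 3] + 1
  expect_true(all(mip_project(v2, "depth")$values >= m))
  # other axes
  expect_equal(mip_project(v, "x")$values, apply(v, c(2, 3), max))
  expect_equal(mip_project(v, "y")$values, apply(v, c(1, 3), max))
})

test_that("en face images of a homogeneous phantom are uniform", {
  sp <- small_phantom(seed = 61, cbi_heterogeneity_db = 0)
  res <- run_pipeline(simulate_volume(sp))
  norm <- normalize_full_thickness(res$env)
  for (layer in c("AC", "CBI")) {
    img <- enface_segment(norm, res$peaks, layer = layer)
    vals <- img$values[!is.na(img$values)]
    expect_equal(length(vals), sum(res$peaks$qc_pass))
    expect_lt(sd(vals) / mean(vals), 0.05)
  }
})

test_that("en face CBI intensity tracks the programmed reflectivity field", {
  sp <- small_phantom(seed = 62, cbi_heterogeneity_db = 3,
                      cbi_heterogeneity_corr_length = 0.2)
  res <- run_pipeline(simulate_volume(sp))
  img <- enface_segment(normalize_full_thickness(res$env), res$peaks,
                        layer = "CBI")
  ok <- !is.na(img$values)
  r <- stats::cor(as.vector(img$values[ok]),
                  as.vector(sp$cbi_reflectivity_field[ok]))
  expect_gt(r, 0.8)
})

test_that("brief decalcification shifts the CBI slab center deeper", {
  sp <- small_phantom(seed = 63, noise_sigma = 0)
  shifted <- apply_decalcification(sp, front_shift = 100, mode = "brief")
  p1 <- run_pipeline(simulate_volume(sp))$peaks
  p2 <- run_pipeline(simulate_volume(shifted))$peaks
  j <- dplyr::inner_join(dplyr::filter(p1, qc_pass),
                         dplyr::filter(p2, qc_pass),
                         by = c("ix", "iy"), suffix = c("_a", "_b"))
  dt_expected <- 2 * 100e-6 / 1600
  dt_sample <- 1 / sp$grid$sampling_rate
  expect_lte(abs(mean(j$cbi_time_b - j$cbi_time_a) - dt_expected), dt_sample)
})

test_that("full decalcification dims the en face CBI image", {
  sp <- small_phantom(seed = 64)
  full <- apply_decalcification(sp, 430, amplitude_drop = 6.63, mode = "full")
  r1 <- run_pipeline(simulate_volume(sp, seed = 640))
  r2 <- run_pipeline(simulate_volume(full, seed = 641))
  # common normalization so pixel values are comparable across scans
  hi <- max(max(r1$env$env), max(r2$env$env))
  scale_norm <- function(res) {
    structure(list(values = res$env$env / hi, grid = res$env$grid),
              class = "qus_norm_volume")
  }
  i1 <- enface_segment(scale_norm(r1), r1$peaks, layer = "CBI")
  i2 <- enface_segment(scale_norm(r2), r2$peaks, layer = "CBI")
  expect_lt(mean(i2$values, na.rm = TRUE), mean(i1$values, na.rm = TRUE))
})

test_that("transverse slices carry a piecewise depth axis", {
  sp <- small_phantom(seed = 65)
  res <- run_pipeline(simulate_volume(sp))
  iy_mid <- floor(sp$grid$n_y / 2) + 1L
  tr <- transverse_slice(res$env, iy_mid, peaks = res$peaks)
  expect_equal(dim(tr$values), c(sp$grid$n_x, sp$grid$n_t))
  # the depth axis at the detected AC surface equals the standoff
  row_peaks <- dplyr::filter(res$peaks, iy == iy_mid, qc_pass)
  i_ac <- round(cbiqus:::time_to_index(stats::median(row_peaks$ac_time),
                                       sp$grid))
  sample_equiv_mm <- 1500 / sp$grid$sampling_rate / 2 * 1000
  expect_lte(abs(tr$depth_axis[i_ac] - sp$standoff_depth), sample_equiv_mm)
  # two bright bands separated by about Delta on the depth axis
  mid_line <- tr$values[6, ]
  i1 <- which.max(mid_line)
  later <- which(cbiqus:::grid_times(sp$grid) >
                   cbiqus:::index_to_time(i1, sp$grid) + 0.5e-6)
  i2 <- later[which.max(mid_line[later])]
  band_sep_mm <- tr$depth_axis[i2] - tr$depth_axis[i1]
  delta_mid <- compute_delta(row_peaks)$delta_mm
  expect_equal(band_sep_mm, mean(delta_mid), tolerance = 0.05)
  # side-effect free
  expect_error(transverse_slice(res$env, 0), "row index")
})

test_that("slabs that reach past the window are clipped and counted", {
  grid <- small_grid()
  sp <- small_phantom(seed = 66)
  res <- run_pipeline(simulate_volume(sp))
  norm <- normalize_full_thickness(res$env)
  # an absurdly wide slab must clip at the window on every accepted line
  img <- enface_segment(norm, res$peaks, layer = "CBI", slab_um = 5e4)
  expect_equal(attr(img, "n_clipped"), sum(res$peaks$qc_pass))
  expect_true(all(!is.na(img$values[cbind(res$peaks$ix[res$peaks$qc_pass],
                                          res$peaks$iy[res$peaks$qc_pass])])))
})
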