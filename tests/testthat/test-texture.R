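test_that("perlin fields are deterministic, bounded and zero at lattice nodes", {
  p <- perlin_params(seed = 11, base_frequency = 8)
  f1 <- perlin_field(p, c(32, 32, 32))
  f2 <- perlin_field(p, c(32, 32, 32))
  expect_identical(f1, f2)
  expect_gte(min(f1), 0)
  expect_lte(max(f1), 1)
  f3 <- perlin_field(perlin_params(seed = 12), c(32, 32, 32))
  expect_false(identical(f1, f3))
  # raw noise vanishes on integer lattice coordinates
  raw <- breastsim:::perlin_grid_cpp(c(4, 4, 4), c(0, 0, 0), 1, 11)
  expect_true(all(raw == 0))
  expect_error(perlin_field(p, c(0, 4, 4)), "positive")
})

test_that("fractal field reduces to a single octave and normalizes amplitudes", {
  p1 <- perlin_params(seed = 5, octaves = 1)
  expect_equal(fractal_field(p1, c(24, 24, 24)), perlin_field(p1, c(24, 24, 24)))
  # vanishing persistence converges to the first octave
  p_eps <- perlin_params(seed = 5, octaves = 4, persistence = 1e-8)
  f_eps <- fractal_field(p_eps, c(24, 24, 24))
  f_one <- perlin_field(perlin_params(seed = 5, octaves = 1, persistence = 1e-8),
                        c(24, 24, 24))
  expect_lt(max(abs(f_eps - f_one)), 1e-6)
  # geometric amplitude sum
  expect_equal(breastsim:::fractal_amplitude(4, 0.5), 1.875)
})

test_that("slab windows tile the same infinite field", {
  p <- perlin_params(seed = 23, octaves = 3)
  whole <- fractal_field(p, c(20, 20, 16), long_edge = 20)
  top <- fractal_field(p, c(20, 20, 8), offset = c(0, 0, 8), long_edge = 20)
  expect_equal(whole[, , 9:16], top)
})

test_that("thresholding obeys the empty/full limits and is monotone", {
  f <- fractal_field(perlin_params(seed = 3), c(64, 64, 64))
  expect_equal(sum(threshold_structures(f, threshold_spec(1))), 0)
  expect_equal(sum(threshold_structures(f, threshold_spec(0))), length(f))
  fractions <- vapply(seq(0, 1, by = 0.1), function(t) {
    mean(threshold_structures(f, threshold_spec(t)))
  }, numeric(1))
  expect_true(all(diff(fractions) <= 0))
  expect_error(threshold_spec(1.2), "\\[0, 1\\]")
  expect_error(threshold_structures(f - 2, threshold_spec(0.5)), "lie in")
})

test_that("raising SF only removes structure voxels (involution inclusion)", {
  spec <- small_spec()
  ph_lo <- build_phantom(spec, sf = 0.98, seed = 6)
  ph_hi <- build_phantom(spec, sf = 1.05, seed = 6)
  gl_lo <- ph_lo$voxels == as.raw(2)
  gl_hi <- ph_hi$voxels == as.raw(2)
  expect_true(all(gl_lo[gl_hi]))           # set inclusion
  expect_lt(sum(gl_hi), sum(gl_lo))
  expect_lt(compute_vbd(ph_hi), compute_vbd(ph_lo))
})

test_that("density calibration levels, curve fit and inversion behave", {
  spec <- small_spec()
  cal <- calibrate_density(spec, sf_levels = c(0.96, 1.0, 1.04),
                           n_phantoms = 3, seed = 17)
  lv <- tidy(cal)
  expect_equal(nrow(lv), 3)
  expect_true(all(diff(lv$mean_vbd) < 0))
  # interpolation fixed point: a calibrated level's mean maps back near its SF
  sf_mid <- sf_for_density(cal, lv$mean_vbd[2])
  expect_lt(abs(sf_mid - lv$sf[2]), 0.02)
  # monotone inversion across falling densities
  targets <- c(lv$mean_vbd[1] * 0.9, lv$mean_vbd[2], lv$mean_vbd[3] * 1.1)
  sfs <- vapply(sort(targets, decreasing = TRUE), sf_for_density, numeric(1),
                cal = cal)
  expect_true(all(diff(sfs) > 0))
  expect_error(sf_for_density(cal, max(lv$mean_vbd) + 10), "outside the calibrated")
  expect_error(calibrate_density(spec, sf_levels = 1), "at least two")
})

test_that("calibration round-trips through delimited text", {
  spec <- small_spec()
  cal <- calibrate_density(spec, sf_levels = c(0.96, 1.0, 1.04),
                           n_phantoms = 2, seed = 19)
  f <- withr::local_tempfile(fileext = ".csv")
  write_calibration(cal, f)
  cal2 <- read_calibration(f)
  expect_equal(tidy(cal2), tidy(cal), tolerance = 1e-9)
  expect_equal(sf_for_density(cal2, 8), sf_for_density(cal, 8), tolerance = 1e-6)
})
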