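test_that("outline volume matches target, including at full scale", {
  # full-scale grid: voxel count is computed analytically, no array needed
  ol_full <- make_outline(848, shape = c(2200, 1200, 600), voxel_mm = 0.1)
  expect_gte(outline_volume_cm3(ol_full), 839.5)
  expect_lte(outline_volume_cm3(ol_full), 856.5)
  # desk scale
  ol <- make_outline(400, shape = c(110, 60, 30), voxel_mm = 2)
  expect_lt(abs(outline_volume_cm3(ol) - 400) / 400, 0.01)
  # mask voxel count agrees with the analytic count
  m <- outline_mask(ol)
  expect_equal(sum(m), ol$n_voxels)
  expect_error(make_outline(0, c(110, 60, 30), 2), "positive")
  expect_error(make_outline(5000, c(110, 60, 30), 2), "does not fit")
})

test_that("halving the resolution scales voxel counts by ~8", {
  ol1 <- make_outline(400, shape = c(110, 60, 30), voxel_mm = 2)
  ol2 <- make_outline(400, shape = c(220, 120, 60), voxel_mm = 1)
  expect_equal(ol2$n_voxels / ol1$n_voxels, 8, tolerance = 0.02)
})

test_that("phantom assembly labels tissue and is reproducible", {
  spec <- small_spec()
  ph <- build_phantom(spec, sf = 1, seed = 4)
  ph2 <- build_phantom(spec, sf = 1, seed = 4)
  expect_identical(ph$voxels, ph2$voxels)
  m <- breast_mask(ph)
  expect_equal(unname(sum(m)), ph$outline$n_voxels)
  # outside voxels all carry the air index
  expect_true(all(ph$voxels[!m] == as.raw(0)))
  idx <- sort(unique(as.integer(ph$voxels)))
  expect_true(all(idx %in% c(0L, 1L, 2L)))
})

test_that("VBD limits for degenerate structure masks", {
  spec <- small_spec()
  # sf high enough that the effective thresholds clamp to 1: no structures
  ph_empty <- build_phantom(spec, sf = 2, seed = 1)
  expect_equal(compute_vbd(ph_empty), 0)
  # sf = 0: thresholds 0, structures everywhere
  ph_full <- build_phantom(spec, sf = 0, seed = 1)
  expect_equal(compute_vbd(ph_full), 100)
})

test_that("compute_vbd equals a voxel-by-voxel accumulation oracle", {
  ph <- toy_phantom(shape = c(20, 18, 16),
                    w = array(runif(16 * 14 * 12), dim = c(16, 14, 12)))
  w <- default_material_table()
  wl <- setNames(w$w_g, w$index)
  idx <- as.integer(ph$voxels)
  acc <- 0; n <- 0
  for (v in idx) {
    if (v == 0) next
    acc <- acc + wl[[as.character(v)]]
    n <- n + 1
  }
  expect_equal(compute_vbd(ph), 100 * acc / n, tolerance = 1e-9)
  # half weight-1, half weight-0 and constant-weight phantoms
  ph50 <- toy_phantom(shape = c(12, 12, 12), w = rep(c(0, 1), length.out = 8^3))
  expect_equal(compute_vbd(ph50), 50)
  ph20 <- toy_phantom(shape = c(12, 12, 12), w = 0.2)
  expect_equal(compute_vbd(ph20), 20)
})

test_that("rotation identity, value closure and exact 90-degree permutation", {
  spec <- phantom_spec(shape = c(40, 40, 40), voxel_mm = 3, volume_cm3 = 300)
  ph <- build_phantom(spec, sf = 1, seed = 8)
  expect_identical(rotate_phantom(ph, c(0, 0, 0))$voxels, ph$voxels)
  r <- rotate_phantom(ph, c(3, 3, 3))
  expect_true(all(unique(as.integer(r$voxels)) %in% unique(as.integer(ph$voxels))))
  # 90 degrees about z on a cubic grid: exact permutation oracle
  r90 <- rotate_phantom(ph, c(0, 0, 90), center = "grid")
  tmp <- aperm(ph$voxels, c(2, 1, 3))
  oracle <- tmp[dim(tmp)[1]:1, , ]
  expect_identical(r90$voxels, oracle)
  expect_equal(compute_vbd(r90), compute_vbd(ph), tolerance = 1e-12)
  # seeded random angles are reproducible
  ra <- rotate_phantom(ph, seed = 5)
  rb <- rotate_phantom(ph, seed = 5)
  expect_identical(ra$voxels, rb$voxels)
  expect_identical(ra$provenance$rotation_deg, rb$provenance$rotation_deg)
})

test_that("phantom save/load round trip is lossless and validates sizes", {
  ph <- toy_phantom(shape = c(10, 10, 10), w = 0.4, voxel_mm = 10)
  f <- withr::local_tempfile(fileext = ".raw")
  save_phantom(ph, f)
  expect_equal(file.size(f), 1000)   # 10x10x10 uint8
  ph2 <- load_phantom(f)
  expect_identical(ph2$voxels, ph$voxels)
  expect_equal(ph2$voxel_mm, ph$voxel_mm)
  expect_equal(compute_vbd(ph2), compute_vbd(ph))
  # truncated raw file rejected
  raw <- readBin(f, "raw", n = 999)
  writeBin(raw, f)
  expect_error(load_phantom(f), "does not match sidecar")
})
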