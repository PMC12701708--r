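# shared small phantom for insertion tests
ins_spec <- phantom_spec(shape = c(60, 40, 30), voxel_mm = 2, volume_cm3 = 80)
ins_ph <- build_phantom(ins_spec, sf = 1, seed = 44)
ins_les <- generate_lesion(8, method = 1, seed = 5, voxel_mm = 2)

test_that("quadrant labels partition the breast and swap with laterality", {
  q <- quadrant_labels(ins_ph)
  m <- breast_mask(ins_ph)
  expect_equal(sum(!is.na(q)), sum(m))             # exactly one label inside
  expect_true(all(is.na(q[!m])))
  counts <- tabulate(q[!is.na(q)], 4)
  # symmetric half-ellipsoid with apex nipple: near-equal quadrants
  expect_lt(max(counts) / min(counts), 1.02 / 0.98)
  qr <- quadrant_labels(ins_ph, laterality = "right")
  cr <- tabulate(qr[!is.na(qr)], 4)
  expect_identical(cr, counts[c(2, 1, 4, 3)])      # UO<->UI, LO<->LI exactly
  expect_error(quadrant_labels(ins_ph, nipple = c(1, 1, 1)), "inside-breast")
})

test_that("quadrant sampling follows the renormalized clinical priors", {
  pol <- insertion_policy()
  expect_equal(sum(pol$renormalized), 1)
  draws <- with(list(), {
    set.seed(321)
    vapply(seq_len(2e4), function(i) sample_quadrant(pol), character(1))
  })
  freq <- table(factor(draws, c("UO", "UI", "LO", "LI"))) / length(draws)
  expect_lt(abs(freq[["UO"]] - 0.585 / 0.925), 0.01)
  # ordering matches the printed priors
  expect_true(freq[["UO"]] > freq[["UI"]] &&
                freq[["UI"]] > freq[["LI"]] &&
                freq[["LI"]] > freq[["LO"]])
  only_uo <- insertion_policy(quadrant_probs = c(UO = 1, UI = 0, LO = 0, LI = 0))
  expect_true(all(vapply(1:20, function(i) sample_quadrant(only_uo, seed = i),
                         character(1)) == "UO"))
  expect_error(insertion_policy(quadrant_probs = c(UO = 0, UI = 0, LO = 0, LI = 0)),
               "positive")
})

test_that("interior erosion hits the volume fraction on an analytic ball", {
  n <- 64; R <- 25
  ax <- seq_len(n) - (n + 1) / 2
  ball <- array(outer(outer(ax^2, ax^2, "+"), ax^2, "+") <= R^2,
                dim = c(n, n, n))
  er <- interior_mask(ball, 0.9)
  frac <- sum(er) / sum(ball)
  expect_gte(frac, 0.88)
  expect_lte(frac, 0.90)
  expect_true(all(ball[er]))                        # subset
  # strictly interior: full 6-neighborhood inside the original mask
  for (a in 1:3) {
    for (s in c(-1, 1)) {
      shifted <- array(FALSE, dim(ball))
      idx <- lapply(dim(ball), seq_len)
      src <- idx
      src[[a]] <- idx[[a]] - s
      ok <- src[[a]] >= 1 & src[[a]] <= dim(ball)[a]
      src[[a]] <- pmin(pmax(src[[a]], 1), dim(ball)[a])
      shifted <- do.call(`[`, c(list(ball), src))
      dim(shifted) <- dim(ball)
      shifted[slice.index(shifted, a) %in% which(!ok)] <- FALSE
      expect_true(all(shifted[er]))
    }
  }
  expect_identical(interior_mask(ball, 1), ball)
  expect_error(interior_mask(ball, 0), "in \\(0, 1\\]")
})

test_that("auto insertion lands inside, respects density support, leaves rest intact", {
  ins <- auto_insert(ins_ph, ins_les, seed = 10)
  expect_true(ins$quadrant %in% c("UO", "UI", "LO", "LI"))
  m <- breast_mask(ins_ph)
  les_vox <- ins$phantom$voxels != ins_ph$voxels
  expect_true(all(m[les_vox]))                     # never outside the breast
  expect_equal(sum(les_vox) <= ins$n_voxels, TRUE)
  # voxels outside the lesion's bounding region bitwise unchanged
  changed <- which(les_vox)
  expect_lte(length(changed), sum(ins_les$occupancy))
  # support restriction: glandular weight only in a posterior y-slab (present
  # in every quadrant, so any sampled quadrant has admissible support)
  w <- array(0, dim = c(36, 36, 36))
  w[, 1:12, ] <- 1
  tp <- toy_phantom(shape = c(40, 40, 40), w = w)
  pol <- insertion_policy(floor = 0, interior_fraction = 0.95)
  les_small <- generate_lesion(4, method = 1, seed = 2, voxel_mm = 1)
  for (s in 1:10) {
    r <- auto_insert(tp, les_small, policy = pol, nipple = c(20, 36, 20), seed = s)
    expect_lte(r$center[2], 15)                    # inside the dense slab
  }
})

test_that("auto insertion center frequencies follow local density weights", {
  # two-density phantom split along y (both regions lie in every quadrant):
  # w = 0.8 posterior half, 0.2 anterior half
  w <- array(0.2, dim = c(36, 36, 36))
  w[, 1:18, ] <- 0.8
  tp <- toy_phantom(shape = c(40, 40, 40), w = w)
  pol <- insertion_policy(floor = 0, interior_fraction = 0.95)
  les_small <- generate_lesion(4, method = 1, seed = 2, voxel_mm = 1)
  post <- vapply(1:400, function(s) {
    auto_insert(tp, les_small, policy = pol, nipple = c(20, 36, 20),
                seed = s)$center[2] <= 20
  }, logical(1))
  p_hat <- mean(post)
  # expected 0.8/(0.8+0.2) = 0.8 up to edge effects of the eroded region;
  # binomial 3 sigma at n=400 is ~0.06
  expect_lt(abs(p_hat - 0.8), 0.08)
})

test_that("manual insertion validates the center and conserves voxel counts", {
  m <- breast_mask(ins_ph)
  inner <- interior_mask(m, 0.9)
  ctr <- breastsim:::linear_to_coord(which(inner)[sum(inner) %/% 2], ins_ph$shape)
  ins <- manual_insert(ins_ph, ins_les, ctr)
  expect_equal(ins$n_voxels, sum(ins_les$occupancy))
  changed <- ins$phantom$voxels != ins_ph$voxels
  expect_lte(sum(changed), sum(ins_les$occupancy))
  # method-1 re-insertion at the same center is idempotent
  ins2 <- manual_insert(ins$phantom, ins_les, ctr)
  expect_identical(ins2$phantom$voxels, ins$phantom$voxels)
  # surface center rejected as subcutaneous
  surf <- breastsim:::linear_to_coord(which(m & !inner)[1], ins_ph$shape)
  expect_error(manual_insert(ins_ph, ins_les, surf), "interior mask")
})

test_that("semi-automatic insertion honors fixed axes and samples the rest", {
  zs <- vapply(1:50, function(s) {
    semi_auto_insert(ins_ph, ins_les, fixed = list(z = 15), seed = s)$center[3]
  }, integer(1))
  expect_true(all(zs == 15))
  # all three fixed behaves like manual insertion at that voxel
  m <- interior_mask(breast_mask(ins_ph), 0.9)
  ctr <- breastsim:::linear_to_coord(which(m)[sum(m) %/% 2], ins_ph$shape)
  a <- semi_auto_insert(ins_ph, ins_les,
                        fixed = list(x = ctr[1], y = ctr[2], z = ctr[3]))
  b <- manual_insert(ins_ph, ins_les, ctr)
  expect_identical(a$phantom$voxels, b$phantom$voxels)
  expect_error(semi_auto_insert(ins_ph, ins_les, fixed = list(z = 1)),
               "no admissible")
  # free axes uniform over the admissible voxels compatible with fixed z
  xs <- vapply(1:300, function(s) {
    semi_auto_insert(ins_ph, ins_les, fixed = list(z = 15), seed = s)$center[1]
  }, integer(1))
  adm <- breastsim:::admissible_centers(ins_ph, ins_les, 0.9)
  adm_x <- apply(adm[, , 15, drop = FALSE], 1, sum)
  bins <- cut(seq_along(adm_x), 4)
  expected <- tapply(adm_x, bins, sum) / sum(adm_x)
  observed <- tapply(tabulate(xs, length(adm_x)), bins, sum)
  chi <- suppressWarnings(chisq.test(observed, p = expected))
  expect_gt(chi$p.value, 1e-4)
})
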