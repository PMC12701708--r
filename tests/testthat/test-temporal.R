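test_that("Method A density passes through its anchors and milestones", {
  p <- trajectory_params_A()
  expect_equal(vbd_method_A(53, p), 10.14)
  expect_equal(vbd_method_A(54, p), 9.89)
  expect_equal(round(vbd_method_A(40, p)), 14)
  expect_equal(vbd_method_A(40, p), 14.03, tolerance = 1e-3)
  expect_equal(round(vbd_method_A(57, p)), 9)
  expect_equal(round(vbd_method_A(74, p)), 6)
  # strictly decreasing over the screening range
  expect_true(all(diff(vbd_method_A(40:74, p)) < 0))
  expect_error(vbd_method_A(39, p), "within")
})

test_that("Method A volume is linear through the anchor", {
  p <- trajectory_params_A()
  expect_equal(volume_method_A(53, p), 848)
  expect_equal(volume_method_A(40, p), 848 - 13 * 14)   # 666
  expect_equal(volume_method_A(74, p), 848 + 21 * 14)   # 1142
  expect_true(all(diff(volume_method_A(40:74, p)) > 0))
})

test_that("Method B applies stepwise group rates year by year", {
  tr1 <- trajectory_method_B(40, 14, 666, ages = 41)
  expect_equal(tr1$vbd, 14 - 0.27)
  expect_equal(tr1$volume, 666 + 16.64)
  # zero rates hold the series constant
  flat <- age_group_rates()
  flat$vbd_change_pp_per_yr <- 0
  flat$volume_change_cm3_per_yr <- 0
  trf <- trajectory_method_B(40, 14, 666, ages = c(50, 60, 74), rates = flat)
  expect_true(all(trf$vbd == 14) && all(trf$volume == 666))
  # total 40->74 volume gain equals the independent group-wise summation
  rates <- age_group_rates()
  gain <- sum(vapply(40:73, function(a) {
    rates$volume_change_cm3_per_yr[rates$age_lo <= a & a <= rates$age_hi]
  }, numeric(1)))
  tr <- trajectory_method_B(40, 14, 666, ages = 74)
  expect_equal(tr$volume - 666, gain)
  expect_equal(gain, 5 * 16.64 + 10 * 18.43 + 10 * 11.68 + 9 * 0.60)
  # continuity across group boundaries: no jumps, only slope changes
  series <- trajectory_method_B(40, 14, 666, ages = seq(44, 46, by = 0.5))
  expect_true(all(abs(diff(series$volume)) < 19 * 0.5 + 1e-9))
})

test_that("Method C draws one annualized change pair from the copula", {
  co <- generate_cohort(cohort_spec(n = 4000, seed = 51))
  fit <- fit_copula(co)
  d1 <- deltas_method_C(fit, seed = 7)
  d2 <- deltas_method_C(fit, seed = 7)
  expect_equal(d1, d2)
  expect_named(d1, c("dvolume_cm3_per_yr", "dvbd_pp_per_yr"))
  # population of draws recovers the marginal mean and the negative
  # volume-density dependence
  draws <- sample_population(fit, 1e4, seed = 3)
  se <- sd(co$dvolume_cm3_per_yr) / sqrt(1e4)
  expect_lt(abs(mean(draws$dvolume_cm3_per_yr) - mean(co$dvolume_cm3_per_yr)),
            4 * se)
  tau <- kendall_tau(draws$dvolume_cm3_per_yr, draws$dvbd_pp_per_yr)
  expect_lt(abs(tau - copula_implied_tau(-0.52)), 0.03)
})

test_that("timelines combine temporal targets, SF inversion and tumor growth", {
  spec <- small_spec()
  cal <- calibrate_density(spec, sf_levels = c(0.95, 0.99, 1.03, 1.07),
                           n_phantoms = 4, seed = 23)
  tl <- build_timeline(ages = c(40, 57, 74), method = "A", calibration = cal,
                       growth = growth_model(5, 282), seed = 2)
  expect_equal(round(tl$target_vbd), c(14, 9, 6))
  expect_true(all(diff(tl$sf) > 0))                  # SF rises as VBD falls
  expect_equal(length(unique(tl$phantom_seed)), 1)   # one noise field per woman
  expect_equal(tl$tumor_mm[1], 5)
  # day-based check at 365 d/yr: ages 40/57 are 6205 days apart
  expect_equal(tl$tumor_mm[2], 5 * (1 + 17 * 365 / 282))
  expect_error(build_timeline(ages = c(40, 39)), "strictly increasing")
  expect_error(build_timeline(ages = c(40, 50, 60), method = "C"),
               "two time points")
})

test_that("fixed-seed phantoms at rising SF realize involution within tolerance", {
  spec <- small_spec()
  cal <- calibrate_density(spec, sf_levels = c(0.95, 0.99, 1.03, 1.07),
                           n_phantoms = 4, seed = 23)
  tl <- build_timeline(ages = c(40, 57, 74), method = "A", calibration = cal,
                       seed = 9)
  phs <- lapply(tl$sf, function(sf) {
    build_phantom(spec, sf = sf, seed = tl$phantom_seed[1])
  })
  gl <- lapply(phs, function(p) p$voxels == as.raw(2))
  # glandular voxel sets only shrink as density declines
  expect_true(all(gl[[1]][gl[[2]]]))
  expect_true(all(gl[[2]][gl[[3]]]))
  achieved <- vapply(phs, compute_vbd, numeric(1))
  tol <- max(2, 3 * max(tidy(cal)$sd_vbd))
  expect_true(all(abs(achieved - tl$target_vbd) <= tol))
})
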