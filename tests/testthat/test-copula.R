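# shared fixture: a moderate synthetic cohort and its fit
cohort_mid <- generate_cohort(cohort_spec(n = 8000, seed = 42))
fit_mid <- fit_copula(cohort_mid)

test_that("kendall_tau matches the O(n^2) pair-count oracle", {
  set.seed(77)
  x <- rnorm(50)
  y <- 0.5 * x + rnorm(50)
  expect_equal(kendall_tau(x, y), brute_tau(x, y))
  # with ties
  xt <- sample(1:8, 60, replace = TRUE)
  yt <- sample(1:5, 60, replace = TRUE)
  expect_equal(kendall_tau(xt, yt), brute_tau(xt, yt))
  # perfect concordance / discordance
  expect_equal(kendall_tau(1:4, 1:4), 1)
  expect_equal(kendall_tau(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_error(kendall_tau(1:3, 1:4), "equal length")
  expect_error(kendall_tau(rep(1, 5), 1:5), "constant")
})

test_that("copula_implied_tau matches its closed form", {
  expect_equal(copula_implied_tau(0), 0)
  expect_equal(copula_implied_tau(-0.52), -0.348136, tolerance = 1e-5)
  expect_equal(copula_implied_tau(0.18), 0.115220, tolerance = 1e-5)
  expect_error(copula_implied_tau(1), "inside")
})

test_that("fit_copula recovers dependence and rejects bad input", {
  expect_lt(abs(fit_mid$rho["breast_volume_cm3", "dense_volume_cm3"] - 0.64), 0.03)
  expect_gt(fit_mid$nu, 2)
  expect_error(fit_copula(cohort_mid[1:20, ]), "at least 50")
  const <- cohort_mid[1:100, ]
  const$age <- 50
  expect_error(fit_copula(const), "age")
})

test_that("independent variables fit to a near-identity correlation", {
  co <- generate_cohort(cohort_spec(n = 1e4, seed = 13, rho = diag(5)))
  f <- fit_copula(co)
  off <- f$rho[upper.tri(f$rho)]
  expect_true(all(abs(off) < 0.03))
})

test_that("kernel margins are monotone and invert over the data range", {
  m <- fit_mid$margins$breast_volume_cm3
  x <- quantile(cohort_mid$breast_volume_cm3, c(0.05, 0.25, 0.5, 0.75, 0.95))
  u <- breastsim:::margin_cdf(m, x)
  expect_true(all(diff(u) > 0))
  x_back <- breastsim:::margin_quantile(m, u)
  expect_equal(unname(x_back), unname(x), tolerance = 0.01)
})

test_that("sampling reproduces the copula-implied tau of every pair", {
  s <- sample_population(fit_mid, 25188, seed = 99)
  vars <- names(fit_mid$margins)
  for (i in 1:4) {
    for (j in (i + 1):5) {
      tau_s <- kendall_tau(s[[vars[i]]], s[[vars[j]]])
      tau_m <- copula_implied_tau(fit_mid$rho[i, j])
      expect_lt(abs(tau_s - tau_m), 0.015)
    }
  }
  expect_true(all(s$breast_volume_cm3 > 0))
  expect_true(all(s$dense_volume_cm3 > 0))
  expect_equal(nrow(sample_population(fit_mid, 0)), 0)
})

test_that("fit -> sample -> fit round trip keeps the correlation stable", {
  s <- sample_population(fit_mid, 8000, seed = 3)
  f2 <- fit_copula(s)
  expect_lt(max(abs(f2$rho - fit_mid$rho)), 0.03)
})

test_that("age stratification honors the tolerance window", {
  co <- generate_cohort(cohort_spec(n = 15000, seed = 21))
  fa <- fit_age_stratified(co, target_age = 40, window = 0.5, min_records = 50)
  used <- co[abs(co$age - 40) <= 0.5, ]
  expect_gte(nrow(used), 50)
  expect_s3_class(fa, "breast_copula")
  expect_equal(fa$n, nrow(used))
  expect_error(fit_age_stratified(co, 57, window = 0), "records within")
  expect_error(fit_age_stratified(co, 20), "within \\[40, 74\\]")
})

test_that("stratified fits are available at every integer screening age", {
  co <- generate_cohort(cohort_spec(n = 15000, seed = 22))
  models <- lapply(40:74, function(a) {
    fit_age_stratified(co, a, window = 0.5, min_records = 30)
  })
  expect_length(models, 35)
  expect_true(all(vapply(models, inherits, logical(1), "breast_copula")))
})

test_that("goodness of fit covers real taus and detects misfit", {
  gof <- goodness_of_fit(fit_mid, cohort_mid, n_replicates = 30, seed = 8)
  expect_equal(nrow(gof$tau_table), 10)  # C(5, 2) pairs
  expect_gte(sum(!gof$tau_table$outside_ci), 8)
  expect_true(all(gof$tau_table$ci_lower <= gof$tau_table$tau_sim_mean))
  expect_true(all(gof$tau_table$tau_sim_mean <= gof$tau_table$ci_upper))
  expect_error(goodness_of_fit(fit_mid, cohort_mid, n_replicates = 1), "at least 2")

  # independence model against a strongly correlated cohort: misfit flagged
  co_ind <- generate_cohort(cohort_spec(n = 3000, seed = 14, rho = diag(5)))
  f_ind <- fit_copula(co_ind)
  gof2 <- goodness_of_fit(f_ind, cohort_mid, n_replicates = 20, seed = 15)
  row <- gof2$tau_table[gof2$tau_table$var1 == "breast_volume_cm3" &
                          gof2$tau_table$var2 == "dense_volume_cm3", ]
  expect_true(row$outside_ci)
})

test_that("tidy and glance summarize fits and reports", {
  td <- tidy(fit_mid)
  expect_equal(nrow(td), 10)
  expect_true(all(c("var1", "var2", "rho", "tau") %in% names(td)))
  gl <- glance(fit_mid)
  expect_equal(gl$n, 8000)
  gof <- goodness_of_fit(fit_mid, cohort_mid, n_replicates = 5, seed = 1)
  expect_s3_class(autoplot(gof), "ggplot")
  expect_equal(glance(gof)$n_pairs, 10)
})
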