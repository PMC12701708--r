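#' Reference parameters of the source screening population
#'
#' Published summary statistics of a population-based Swedish digital
#' mammography screening cohort (25,188 women, ages 40--74, two consecutive
#' screening rounds): per-variable marginal moments, the t-copula correlation
#' matrix of the five modeled variables, and the copula degrees of freedom.
#' These are the default inputs of [cohort_spec()], so a fully synthetic
#' cohort with the dependence structure of the real screening population can
#' be generated without any data download.
#'
#' The five variables, in the order used by the correlation matrix, are:
#' breast volume (cm^3), dense volume (cm^3), age (years), annualized change
#' in breast volume (cm^3/year), and annualized change in volumetric breast
#' density (percentage points/year). The published table labels the density
#' change in cm^3, but the surrounding text and the age-group rate tables
#' treat it as percentage points per year; the latter unit is used here.
#'
#' @return A list with elements `marginals` (tibble: variable, mean, sd,
#'   dist), `rho` (5x5 correlation matrix), `nu` (degrees of freedom), and
#'   `n` (source cohort size).
#' @export
#' @examples
#' screening_reference()$marginals
screening_reference <- function() {
  vars <- cohort_variables()
  marginals <- tibble::tibble(
    variable = vars,
    mean = c(848, 74, 53, 14, 0.5),
    sd = c(495, 42, 10, 95, 11),
    dist = c("lognormal", "lognormal", "truncnorm", "normal", "normal")
  )
  rho <- matrix(c(
    1.00,  0.64,  0.18, -0.05,  0.07,
    0.64,  1.00, -0.16, -0.04, -0.20,
    0.18, -0.16,  1.00, -0.07,  0.02,
    -0.05, -0.04, -0.07,  1.00, -0.52,
    0.07, -0.20,  0.02, -0.52,  1.00
  ), nrow = 5, byrow = TRUE, dimnames = list(vars, vars))
  list(marginals = marginals, rho = rho, nu = 16.44, n = 25188L)
}

#' Cohort variable and column orders
#'
#' `cohort_variables()` is the canonical variable order used by the copula
#' correlation matrix; `cohort_columns()` is the column order of cohort
#' CSV files.
#'
#' @return Character vector of the five cohort variable names.
#' @export
cohort_variables <- function() {
  c("breast_volume_cm3", "dense_volume_cm3", "age",
    "dvolume_cm3_per_yr", "dvbd_pp_per_yr")
}

#' @rdname cohort_variables
#' @export
cohort_columns <- function() {
  c("age", "breast_volume_cm3", "dense_volume_cm3",
    "dvolume_cm3_per_yr", "dvbd_pp_per_yr")
}

#' Specify a synthetic screening cohort
#'
#' Bundles everything [generate_cohort()] needs: the number of women, the RNG
#' seed, per-variable marginal moments on the natural scale, the t-copula
#' correlation matrix and degrees of freedom, and the screening age range.
#' Defaults reproduce the published screening population
#' (see [screening_reference()]).
#'
#' @param n Number of women to simulate.
#' @param seed Integer RNG seed.
#' @param marginals Tibble with columns `variable`, `mean`, `sd`, `dist`
#'   (one of `"lognormal"`, `"normal"`, `"truncnorm"`), one row per cohort
#'   variable.
#' @param rho 5x5 copula correlation matrix (symmetric, unit diagonal,
#'   positive definite), variables ordered as in [cohort_variables()].
#' @param nu Copula degrees of freedom (> 2).
#' @param age_range Screening age limits used to truncate the age margin.
#' @param age40_spike Optional mixture weight in `[0, 1)`: probability mass
#'   moved onto exact age 40, emulating the administrative pile-up of
#'   first-invitation ages seen in real screening registers. Off by default.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n,
                        seed = 1L,
                        marginals = screening_reference()$marginals,
                        rho = screening_reference()$rho,
                        nu = screening_reference()$nu,
                        age_range = c(40, 74),
                        age40_spike = 0) {
  if (!is_count(n)) stop_bs("`n` must be a non-negative integer")
  if (!is_scalar_num(nu) || nu <= 2) stop_bs("`nu` must be > 2")
  if (!is.matrix(rho) || any(dim(rho) != 5)) stop_bs("`rho` must be a 5x5 matrix")
  if (max(abs(rho - t(rho))) > 1e-12) stop_bs("`rho` must be symmetric")
  if (any(abs(diag(rho) - 1) > 1e-12)) stop_bs("`rho` must have a unit diagonal")
  ev <- eigen(rho, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) stop_bs("`rho` must be positive definite")
  stopifnot(is.data.frame(marginals),
            all(c("variable", "mean", "sd", "dist") %in% names(marginals)))
  marginals <- marginals[match(cohort_variables(), marginals$variable), ]
  if (anyNA(marginals$variable)) stop_bs("`marginals` must cover all five cohort variables")
  vol <- marginals$dist == "lognormal"
  if (any(marginals$sd[vol] <= 0) || any(marginals$mean[vol] <= 0)) {
    stop_bs("volume variables need positive mean and sd")
  }
  if (any(marginals$sd <= 0)) stop_bs("marginal sds must be positive")
  if (!is.numeric(age_range) || length(age_range) != 2 || diff(age_range) <= 0) {
    stop_bs("`age_range` must be increasing limits")
  }
  if (!is_scalar_num(age40_spike) || age40_spike < 0 || age40_spike >= 1) {
    stop_bs("`age40_spike` must be in [0, 1)")
  }
  structure(
    list(n = as.integer(n), seed = as.integer(seed), marginals = marginals,
         rho = rho, nu = nu, age_range = age_range, age40_spike = age40_spike),
    class = "cohort_spec"
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec> n =", x$n, " nu =", format(x$nu),
      " seed =", x$seed, "\n")
  invisible(x)
}

#' Moment-matched lognormal parameters
#'
#' Log-scale parameters of the lognormal distribution whose natural-scale
#' mean and standard deviation match the given moments:
#' `sdlog^2 = log(1 + sd^2/mean^2)`, `meanlog = log(mean) - sdlog^2 / 2`.
#'
#' @param mean,sd Target natural-scale mean and standard deviation (`mean > 0`,
#'   `sd > 0`).
#' @return Named list with `meanlog` and `sdlog`.
#' @export
#' @examples
#' lognormal_moments(848, 495)
lognormal_moments <- function(mean, sd) {
  if (mean <= 0 || sd <= 0) stop_bs("`mean` and `sd` must be positive")
  s2 <- log(1 + sd^2 / mean^2)
  list(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

# Draw n rows of copula-uniform variates from a t-copula.
# Returns an n x d matrix of values in (0, 1).
sample_t_copula <- function(n, rho, nu) {
  d <- ncol(rho)
  if (n == 0) return(matrix(numeric(0), 0, d))
  z <- matrix(rnorm(n * d), n, d) %*% chol(rho)
  w <- rchisq(n, df = nu) / nu
  pt(z / sqrt(w), df = nu)
}

# quantile function of a truncated normal on [lo, hi]
qtruncnorm <- function(p, mean, sd, lo, hi) {
  plo <- pnorm(lo, mean, sd)
  phi <- pnorm(hi, mean, sd)
  qnorm(plo + p * (phi - plo), mean, sd)
}

#' Generate a synthetic screening cohort
#'
#' Samples `n` virtual women from a t-copula with the given correlation
#' matrix and degrees of freedom, then maps the copula-uniform variates
#' through moment-matched margins: lognormal for breast volume and dense
#' volume (guaranteeing positivity), a truncated normal over the screening
#' age range for age, and normals for the two annualized change variables
#' (which take both signs). Dense volume is capped at breast volume so every
#' record satisfies the physical constraint `dense <= breast`.
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with one row per woman and columns
#'   `age`, `breast_volume_cm3`, `dense_volume_cm3`, `dvolume_cm3_per_yr`,
#'   `dvbd_pp_per_yr`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_spec(n = 500, seed = 7))
#' dplyr::summarise(cohort, mean(breast_volume_cm3), mean(age))
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  vars <- cohort_variables()
  if (spec$n == 0) {
    out <- tibble::as_tibble(setNames(rep(list(numeric(0)), 5), cohort_columns()))
    return(out)
  }
  with_seed(spec$seed, {
    u <- sample_t_copula(spec$n, spec$rho, spec$nu)
    cols <- vector("list", 5)
    names(cols) <- vars
    for (j in seq_along(vars)) {
      m <- spec$marginals[j, ]
      cols[[j]] <- switch(
        m$dist,
        lognormal = {
          lp <- lognormal_moments(m$mean, m$sd)
          stats::qlnorm(u[, j], lp$meanlog, lp$sdlog)
        },
        truncnorm = qtruncnorm(u[, j], m$mean, m$sd,
                               spec$age_range[1], spec$age_range[2]),
        normal = qnorm(u[, j], m$mean, m$sd),
        stop_bs("unknown marginal distribution: ", m$dist)
      )
    }
    cols$dense_volume_cm3 <- pmin(cols$dense_volume_cm3, cols$breast_volume_cm3)
    if (spec$age40_spike > 0) {
      hit <- runif(spec$n) < spec$age40_spike
      cols$age[hit] <- spec$age_range[1]
    }
    tibble::as_tibble(cols)[, cohort_columns()]
  })
}

#' Read and write cohort tables
#'
#' Cohorts are exchanged as plain CSV with a fixed header
#' (`age, breast_volume_cm3, dense_volume_cm3, dvolume_cm3_per_yr,
#' dvbd_pp_per_yr`).
#'
#' @param cohort A cohort tibble (as from [generate_cohort()]).
#' @param path File path.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()` returns
#'   the cohort tibble.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(all(cohort_columns() %in% names(cohort)))
  readr::write_csv(cohort[, cohort_columns()], path)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  out <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_double()))
  miss <- setdiff(cohort_columns(), names(out))
  if (length(miss)) stop_bs("cohort file is missing columns: ", paste(miss, collapse = ", "))
  out[, cohort_columns()]
}
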