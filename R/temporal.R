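#' Population-level trajectory anchors (Method A)
#'
#' Anchors of the whole-population temporal models: at the cohort mean age
#' of 53 years the mean volumetric breast density is 10.14% and declines by
#' 0.25 percentage points over the following year, while the mean breast
#' volume is 848 cm^3 and grows by 14 cm^3 per year. Density follows an
#' exponential in age through the two density anchor points; volume is
#' linear in age.
#'
#' @param anchor_age Anchor age in years.
#' @param anchor_vbd Mean VBD% at the anchor age.
#' @param annual_vbd_change First-year VBD change in percentage points
#'   (negative = involution).
#' @param anchor_volume Mean breast volume (cm^3) at the anchor age.
#' @param annual_volume_change Volume change in cm^3 per year.
#' @return An object of class `trajectory_params_A`.
#' @export
trajectory_params_A <- function(anchor_age = 53, anchor_vbd = 10.14,
                                annual_vbd_change = -0.25,
                                anchor_volume = 848,
                                annual_volume_change = 14) {
  if (anchor_vbd <= 0 || anchor_volume <= 0) {
    stop_bs("anchor VBD and volume must be positive")
  }
  if (anchor_vbd + annual_vbd_change <= 0) {
    stop_bs("annual VBD change would drive density non-positive within a year")
  }
  structure(
    list(anchor_age = anchor_age, anchor_vbd = anchor_vbd,
         annual_vbd_change = annual_vbd_change,
         anchor_volume = anchor_volume,
         annual_volume_change = annual_volume_change),
    class = "trajectory_params_A"
  )
}

check_model_age <- function(age, lo = 40, hi = 74) {
  if (any(!is.finite(age)) || any(age < lo) || any(age > hi)) {
    stop_bs("age must lie within the screening range [", lo, ", ", hi, "]")
  }
  age
}

#' Method A: exponential density decline over age
#'
#' `VBD(age) = anchor_vbd * exp(rate * (age - anchor_age))` with
#' `rate = log((anchor_vbd + annual_vbd_change) / anchor_vbd)` fixed by the
#' two anchor points, so the curve passes exactly through (53, 10.14%) and
#' (54, 9.89%) under the defaults. At the Swedish screening milestones this
#' yields 14% at inclusion (age 40), 9% at midpoint (57) and 6% at exit
#' (74), after rounding to integer percent.
#'
#' @param age Age(s) in years, within `[40, 74]`; vectorized.
#' @param p A [trajectory_params_A()].
#' @return VBD in percent.
#' @export
#' @examples
#' round(vbd_method_A(c(40, 57, 74)))
vbd_method_A <- function(age, p = trajectory_params_A()) {
  stopifnot(inherits(p, "trajectory_params_A"))
  check_model_age(age)
  r <- log((p$anchor_vbd + p$annual_vbd_change) / p$anchor_vbd)
  p$anchor_vbd * exp(r * (age - p$anchor_age))
}

#' Method A: linear breast-volume growth over age
#'
#' `V(age) = anchor_volume + annual_volume_change * (age - anchor_age)`.
#'
#' @inheritParams vbd_method_A
#' @return Breast volume in cm^3.
#' @export
#' @examples
#' volume_method_A(c(40, 53, 74))
volume_method_A <- function(age, p = trajectory_params_A()) {
  stopifnot(inherits(p, "trajectory_params_A"))
  check_model_age(age)
  p$anchor_volume + p$annual_volume_change * (age - p$anchor_age)
}

#' Age-group rates for the stepwise temporal model (Method B)
#'
#' Clinically observed annualized changes by age group: VBD change in
#' percentage points per year and breast-volume change in cm^3 per year.
#' Groups are contiguous and cover the whole screening range 40--74.
#'
#' @return Tibble with columns `age_lo`, `age_hi`, `vbd_change_pp_per_yr`,
#'   `volume_change_cm3_per_yr`.
#' @export
age_group_rates <- function() {
  tibble::tibble(
    age_lo = c(40, 45, 55, 65),
    age_hi = c(44, 54, 64, 74),
    vbd_change_pp_per_yr = c(-0.27, -0.38, -0.15, -0.028),
    volume_change_cm3_per_yr = c(16.64, 18.43, 11.68, 0.60)
  )
}

rate_for_age <- function(rates, age) {
  i <- which(rates$age_lo <= age & age <= rates$age_hi)
  if (!length(i)) stop_bs("age ", age, " is outside the rate-table coverage")
  rates[i[1], ]
}

#' Method B: stepwise (piecewise) trajectories by age group
#'
#' Year-by-year integration from the starting state: over the year
#' `[a, a + 1)` the rates of the group containing integer age `a` apply.
#' VBD changes are realized as a re-anchored exponential per year -- the
#' decrement over one full year equals the group's percentage-point rate
#' exactly, so the first simulated year reproduces the tabulated change --
#' and volume changes accumulate linearly. Fractional final years are
#' prorated.
#'
#' @param start_age Starting age (years), at most `min(ages)`.
#' @param start_vbd Starting VBD in percent.
#' @param start_volume Starting breast volume in cm^3.
#' @param ages Evaluation ages (non-decreasing, within the rate coverage).
#' @param rates Rate table, see [age_group_rates()].
#' @return Tibble with columns `age`, `vbd`, `volume`.
#' @export
#' @examples
#' trajectory_method_B(40, 14, 666, ages = c(41, 45, 74))
trajectory_method_B <- function(start_age, start_vbd, start_volume, ages,
                                rates = age_group_rates()) {
  if (any(diff(ages) < 0)) stop_bs("`ages` must be non-decreasing")
  if (start_age > min(ages)) stop_bs("`start_age` must not exceed the first age")
  check_model_age(c(start_age, ages), min(rates$age_lo), max(rates$age_hi) + 1)
  vbd <- start_vbd
  vol <- start_volume
  a <- start_age
  out_vbd <- numeric(length(ages))
  out_vol <- numeric(length(ages))
  for (i in seq_along(ages)) {
    while (a < ages[i]) {
      to_boundary <- if (a %% 1 == 0) 1 else ceiling(a) - a
      step <- min(ages[i] - a, to_boundary)
      rt <- rate_for_age(rates, floor(a))
      # re-anchored exponential: full-year multiplier (vbd + rate)/vbd
      vbd <- vbd * ((vbd + rt$vbd_change_pp_per_yr) / vbd)^step
      vol <- vol + rt$volume_change_cm3_per_yr * step
      a <- a + step
    }
    out_vbd[i] <- vbd
    out_vol[i] <- vol
  }
  tibble::tibble(age = ages, vbd = out_vbd, volume = out_vol)
}

#' Method C: sample individual annual changes from the fitted copula
#'
#' Draws one joint sample from the fitted t-copula and returns its two
#' annualized change variables. This respects the (negative) dependence
#' between volume change and density change seen in the cohort, and is
#' intended for exactly one inter-screen interval: iterating individual
#' draws over many rounds accumulates random variation that the
#' population-level Methods A and B deliberately avoid.
#'
#' @param model A `breast_copula` from [fit_copula()].
#' @param woman Optional single cohort record (carried through to the
#'   output for bookkeeping; the draw itself is a joint copula sample, not
#'   conditioned on the woman's covariates).
#' @param seed Optional RNG seed.
#' @return One-row tibble with `dvolume_cm3_per_yr` and `dvbd_pp_per_yr`.
#' @export
deltas_method_C <- function(model, woman = NULL, seed = NULL) {
  stopifnot(inherits(model, "breast_copula"))
  s <- sample_population(model, 1, seed = seed)
  out <- s[, c("dvolume_cm3_per_yr", "dvbd_pp_per_yr")]
  if (!is.null(woman) && !is.null(woman$woman_id)) out$woman_id <- woman$woman_id
  out
}

#' Build a per-age phantom/lesion schedule for one virtual woman
#'
#' Computes the target VBD and breast volume at each evaluation age with the
#' chosen temporal method, converts each density target into a threshold
#' scaling factor through the density calibration, and (optionally) attaches
#' the tumor diameter from the growth model, with age differences converted
#' at 365 days per year. The phantom seed is fixed per woman, so phantoms at
#' successive ages share one noise field and rising SF realizes tissue
#' involution on the same anatomy (structures only ever disappear).
#'
#' @param woman List or one-row tibble; may carry `woman_id`, and for
#'   Methods B/C the starting `vbd` and `volume` (defaults: Method A values
#'   at the first age).
#' @param ages Strictly increasing evaluation ages within `[40, 74]`.
#' @param method `"A"`, `"B"` or `"C"`.
#' @param calibration Optional [calibrate_density()] result; when supplied,
#'   an `sf` column is added (errors if a target density is outside the
#'   calibrated range).
#' @param growth Optional [growth_model()]; adds a `tumor_mm` column.
#' @param model `breast_copula`, required for Method C (which is restricted
#'   to two ages, i.e. two consecutive screening rounds).
#' @param params_A Method A anchors.
#' @param rates Method B rate table.
#' @param seed Integer seed; fixes the per-woman phantom seed and the
#'   Method C draw.
#' @return A `breast_timeline` tibble: one row per age with `woman_id`,
#'   `age`, `target_vbd`, `target_volume`, `phantom_seed`, plus `sf` and/or
#'   `tumor_mm` when requested.
#' @export
build_timeline <- function(woman = list(woman_id = 1L), ages,
                           method = c("A", "B", "C"),
                           calibration = NULL, growth = NULL, model = NULL,
                           params_A = trajectory_params_A(),
                           rates = age_group_rates(), seed = 1L) {
  method <- match.arg(method)
  if (length(ages) < 1 || any(diff(ages) <= 0)) {
    stop_bs("`ages` must be strictly increasing")
  }
  check_model_age(ages)
  woman_id <- if (!is.null(woman$woman_id)) woman$woman_id else 1L

  if (method == "A") {
    vbd <- vbd_method_A(ages, params_A)
    vol <- volume_method_A(ages, params_A)
  } else {
    start_vbd <- if (!is.null(woman$vbd)) woman$vbd else vbd_method_A(ages[1], params_A)
    start_vol <- if (!is.null(woman$volume)) woman$volume else volume_method_A(ages[1], params_A)
    if (method == "B") {
      tr <- trajectory_method_B(ages[1], start_vbd, start_vol, ages, rates)
      vbd <- tr$vbd
      vol <- tr$volume
    } else {
      if (length(ages) > 2) {
        stop_bs("Method C samples one inter-screen change and is restricted ",
                "to two time points; use Method A or B for longer timelines")
      }
      if (is.null(model)) stop_bs("Method C requires a fitted `model`")
      dl <- deltas_method_C(model, woman, seed = derive_seed(seed, 17L))
      dt <- diff(ages)
      vbd <- c(start_vbd, if (length(dt)) start_vbd + dl$dvbd_pp_per_yr * dt)
      vol <- c(start_vol, if (length(dt)) start_vol + dl$dvolume_cm3_per_yr * dt)
    }
  }
  out <- tibble::tibble(
    woman_id = woman_id, age = ages,
    target_vbd = vbd, target_volume = vol,
    phantom_seed = derive_seed(seed, 1000L + as.integer(woman_id))
  )
  if (!is.null(growth)) {
    stopifnot(inherits(growth, "growth_model"))
    out$tumor_mm <- grown_diameter(growth, (ages - ages[1]) * 365)
  }
  if (!is.null(calibration)) {
    out$sf <- vapply(out$target_vbd, function(v) sf_for_density(calibration, v),
                     numeric(1))
  }
  attr(out, "method") <- method
  class(out) <- c("breast_timeline", class(out))
  out
}

#' Plot a timeline
#'
#' Density, volume and (if present) tumor-diameter trajectories over age.
#'
#' @param object A `breast_timeline`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.breast_timeline <- function(object, ...) {
  df <- tibble::as_tibble(object)
  keep <- intersect(c("target_vbd", "target_volume", "tumor_mm"), names(df))
  long <- tidyr::pivot_longer(df[, c("age", keep)], -"age",
                              names_to = "quantity", values_to = "value")
  labels <- c(target_vbd = "VBD (%)", target_volume = "breast volume (cm^3)",
              tumor_mm = "tumor diameter (mm)")
  long$quantity <- labels[long$quantity]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$age, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "age (years)", y = NULL) +
    ggplot2::theme_minimal()
}
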