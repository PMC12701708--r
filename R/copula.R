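#' Kendall rank correlation (tau-b)
#'
#' Tie-corrected Kendall rank correlation computed with Knight's
#' O(n log n) merge-sort algorithm, so it stays fast at screening-cohort
#' sizes (tens of thousands of records) where the naive pair count is
#' prohibitive.
#'
#' @param x,y Numeric vectors of equal length (>= 2).
#' @return The tau-b statistic in `[-1, 1]`.
#' @export
#' @examples
#' kendall_tau(1:4, c(2, 1, 4, 3))
kendall_tau <- function(x, y) {
  if (length(x) != length(y)) stop_bs("`x` and `y` must have equal length")
  if (length(x) < 2) stop_bs("need at least two observations")
  if (anyNA(x) || anyNA(y)) stop_bs("missing values are not supported")
  kendall_tau_cpp(as.numeric(x), as.numeric(y))
}

#' Kendall tau implied by an elliptical-copula correlation
#'
#' For elliptical copulas (Gaussian, Student-t) the population Kendall tau of
#' a pair is `tau = (2/pi) * asin(rho)`. Used as the analytic oracle when
#' validating copula fitting and sampling.
#'
#' @param rho_ij Pairwise copula correlation, strictly inside `(-1, 1)`.
#' @return Implied Kendall tau.
#' @export
#' @examples
#' copula_implied_tau(0.64)
copula_implied_tau <- function(rho_ij) {
  if (any(!is.finite(rho_ij)) || any(abs(rho_ij) >= 1)) {
    stop_bs("`rho_ij` must lie strictly inside (-1, 1)")
  }
  (2 / pi) * asin(rho_ij)
}

# ---- kernel-smoothed margins -------------------------------------------

# Gaussian-kernel CDF estimate evaluated on a dense grid; invertible by
# monotone interpolation. Silverman's rule for the bandwidth.
kernel_margin <- function(x, log_transform = FALSE, grid_n = 1024) {
  if (log_transform) x <- log(x)
  n <- length(x)
  s <- stats::sd(x)
  iqr <- stats::IQR(x)
  bw <- 0.9 * min(s, if (iqr > 0) iqr / 1.34 else s) * n^(-1 / 5)
  if (!is.finite(bw) || bw <= 0) stop_bs("degenerate bandwidth (constant variable?)")
  grid <- seq(min(x) - 3 * bw, max(x) + 3 * bw, length.out = grid_n)
  cdf <- numeric(grid_n)
  chunk <- 64L
  for (i0 in seq(1, grid_n, by = chunk)) {
    i1 <- min(i0 + chunk - 1L, grid_n)
    g <- grid[i0:i1]
    cdf[i0:i1] <- colMeans(pnorm(outer(x, g, function(a, b) (b - a) / bw)))
  }
  list(grid = grid, cdf = cdf, bw = bw, log_transform = log_transform,
       range = range(x))
}

margin_cdf <- function(margin, x) {
  if (margin$log_transform) x <- log(x)
  approx(margin$grid, margin$cdf, xout = x, rule = 2)$y
}

margin_quantile <- function(margin, u) {
  q <- approx(margin$cdf, margin$grid, xout = u, rule = 2)$y
  if (margin$log_transform) exp(q) else q
}

# ---- correlation-matrix utilities --------------------------------------

# nearest positive-definite correlation matrix by eigenvalue clipping
nearest_pd_corr <- function(m, eps = 1e-6) {
  for (i in 1:10) {
    e <- eigen(m, symmetric = TRUE)
    if (min(e$values) > eps) break
    vals <- pmax(e$values, eps)
    m <- e$vectors %*% diag(vals) %*% t(e$vectors)
    d <- sqrt(diag(m))
    m <- m / tcrossprod(d)
    m <- (m + t(m)) / 2
    diag(m) <- 1
  }
  m
}

# profile log pseudo-likelihood of the t-copula in nu, margins fixed
t_copula_loglik <- function(nu, u, rho) {
  d <- ncol(u)
  q <- qt(u, df = nu)
  L <- chol(rho)
  a <- backsolve(L, t(q), transpose = TRUE)  # solves t(L) a = t(q)
  m <- colSums(a^2)
  ld <- 2 * sum(log(diag(L)))
  n <- nrow(u)
  n * (lgamma((nu + d) / 2) + (d - 1) * lgamma(nu / 2) -
         d * lgamma((nu + 1) / 2) - 0.5 * ld) -
    ((nu + d) / 2) * sum(log1p(m / nu)) +
    ((nu + 1) / 2) * sum(log1p(q^2 / nu))
}

#' Fit a t-copula with kernel-smoothed margins to a screening cohort
#'
#' Estimates the dependence structure of the five cohort variables (breast
#' volume, dense volume, age, annualized volume change, annualized density
#' change) by pseudo-maximum likelihood: each margin is turned into
#' pseudo-observations via a Gaussian-kernel smoothed CDF (the two volume
#' variables are log-transformed first to keep back-transformed samples
#' positive), the copula correlation matrix is obtained by Kendall-tau
#' inversion (`rho = sin(pi * tau / 2)`) projected to the nearest positive
#' definite correlation matrix, and the degrees of freedom are estimated by
#' profiling the t-copula pseudo-likelihood over `(2, 100]`.
#'
#' @param records Cohort tibble with the columns of [cohort_columns()].
#' @param log_vars Variables log-transformed before margin estimation.
#' @param min_records Minimum number of complete records required.
#' @return An object of class `breast_copula` with elements `rho`, `nu`,
#'   `margins`, `log_vars`, `n`, `loglik`.
#' @seealso [sample_population()], [goodness_of_fit()], [tidy.breast_copula()]
#' @export
fit_copula <- function(records,
                       log_vars = c("breast_volume_cm3", "dense_volume_cm3"),
                       min_records = 50) {
  vars <- cohort_variables()
  miss <- setdiff(vars, names(records))
  if (length(miss)) stop_bs("`records` is missing columns: ", paste(miss, collapse = ", "))
  x <- as.data.frame(records)[, vars]
  if (anyNA(x)) stop_bs("`records` contains missing values")
  if (nrow(x) < min_records) {
    stop_bs("need at least ", min_records, " records, got ", nrow(x))
  }
  for (v in vars) {
    if (stats::sd(x[[v]]) == 0) stop_bs("variable has zero variance: ", v)
  }

  n <- nrow(x)
  margins <- lapply(vars, function(v) kernel_margin(x[[v]], v %in% log_vars))
  names(margins) <- vars

  u <- vapply(vars, function(v) {
    margin_cdf(margins[[v]], x[[v]]) * n / (n + 1)
  }, numeric(n))
  u <- clamp(u, 1e-10, 1 - 1e-10)

  d <- length(vars)
  tau <- diag(1, d)
  for (i in 1:(d - 1)) {
    for (j in (i + 1):d) {
      tau[i, j] <- tau[j, i] <- kendall_tau_cpp(u[, i], u[, j])
    }
  }
  rho <- sin(pi * tau / 2)
  diag(rho) <- 1
  rho <- nearest_pd_corr(rho)
  dimnames(rho) <- list(vars, vars)

  opt <- optimize(function(lnu) -t_copula_loglik(exp(lnu), u, rho),
                  interval = c(log(2.05), log(100)), tol = 1e-4)
  nu <- exp(opt$minimum)

  structure(
    list(rho = rho, nu = nu, margins = margins, log_vars = log_vars,
         n = n, loglik = -opt$objective),
    class = "breast_copula"
  )
}

#' @export
print.breast_copula <- function(x, ...) {
  cat("<breast_copula> fitted to", x$n, "records; nu =",
      format(x$nu, digits = 4), "\n")
  cat("rho:\n")
  print(round(x$rho, 3))
  invisible(x)
}

#' Tidy a fitted t-copula
#'
#' @param x A `breast_copula`.
#' @param ... Unused.
#' @return A tibble with one row per variable pair: `var1`, `var2`, `rho`,
#'   and the copula-implied Kendall `tau`.
#' @export
tidy.breast_copula <- function(x, ...) {
  vars <- rownames(x$rho)
  d <- length(vars)
  idx <- which(upper.tri(x$rho), arr.ind = TRUE)
  tibble::tibble(
    var1 = vars[idx[, 1]],
    var2 = vars[idx[, 2]],
    rho = x$rho[idx],
    tau = copula_implied_tau(clamp(x$rho[idx], -1 + 1e-12, 1 - 1e-12))
  )
}

#' @rdname tidy.breast_copula
#' @export
glance.breast_copula <- function(x, ...) {
  tibble::tibble(nu = x$nu, n = x$n, logLik = x$loglik,
                 log_vars = paste(x$log_vars, collapse = ","))
}

#' Sample a virtual population from a fitted copula
#'
#' Draws from the fitted t-copula and inverts each kernel-smoothed margin
#' (exponentiating the log-transformed volume variables), so virtual records
#' reproduce both the marginal distributions and the dependence structure of
#' the source cohort without copying any original record. Dense volume is
#' capped at breast volume.
#'
#' @param model A `breast_copula` from [fit_copula()].
#' @param n Number of virtual women.
#' @param seed Optional RNG seed.
#' @return A cohort tibble (same schema as [generate_cohort()]).
#' @export
sample_population <- function(model, n, seed = NULL) {
  stopifnot(inherits(model, "breast_copula"))
  if (!is_count(n)) stop_bs("`n` must be a non-negative integer")
  vars <- cohort_variables()
  if (n == 0) {
    return(tibble::as_tibble(setNames(rep(list(numeric(0)), 5), cohort_columns())))
  }
  with_seed(seed, {
    u <- sample_t_copula(n, model$rho, model$nu)
    cols <- lapply(seq_along(vars), function(j) {
      margin_quantile(model$margins[[vars[j]]], u[, j])
    })
    names(cols) <- vars
    cols$dense_volume_cm3 <- pmin(cols$dense_volume_cm3, cols$breast_volume_cm3)
    tibble::as_tibble(cols)[, cohort_columns()]
  })
}

#' Fit an age-stratified copula
#'
#' Restricts the cohort to records within `window` years of `target_age`
#' (the screening register invites some women slightly before their birthday,
#' hence the tolerance window) and fits the copula to that stratum.
#'
#' @inheritParams fit_copula
#' @param target_age Target age in years, within `[40, 74]`.
#' @param window Half-width of the age tolerance window in years.
#' @return A `breast_copula`.
#' @export
fit_age_stratified <- function(records, target_age, window = 0.5,
                               min_records = 50) {
  if (!is_scalar_num(target_age) || target_age < 40 || target_age > 74) {
    stop_bs("`target_age` must be within [40, 74]")
  }
  keep <- abs(records$age - target_age) <= window
  m <- sum(keep)
  if (m < min_records) {
    stop_bs("only ", m, " records within ", window, " years of age ",
            target_age, " (need ", min_records, ")")
  }
  fit_copula(records[keep, , drop = FALSE], min_records = min_records)
}

#' Bootstrap goodness of fit of a copula population model
#'
#' Samples `n_replicates` virtual populations of the same size as the source
#' cohort, then compares (i) per-variable means and SDs averaged over
#' replicates against the real cohort and (ii) the per-pair mean simulated
#' Kendall tau and its 2.5--97.5 percentile interval against the real tau.
#'
#' @param model A `breast_copula`.
#' @param records The source cohort tibble.
#' @param n_replicates Number of virtual populations (>= 2).
#' @param seed Optional RNG seed.
#' @return A `gof_report` with tibbles `marginal_table` and `tau_table`
#'   (the latter flags pairs whose real tau falls outside the simulated
#'   interval) and `n_replicates`.
#' @export
goodness_of_fit <- function(model, records, n_replicates = 100, seed = NULL) {
  stopifnot(inherits(model, "breast_copula"))
  if (!is_count(n_replicates) || n_replicates < 2) {
    stop_bs("`n_replicates` must be at least 2")
  }
  vars <- cohort_variables()
  x <- as.data.frame(records)[, vars]
  n <- nrow(x)
  d <- length(vars)
  pairs <- which(upper.tri(diag(d)), arr.ind = TRUE)
  np <- nrow(pairs)

  tau_real <- vapply(seq_len(np), function(p) {
    kendall_tau_cpp(x[[pairs[p, 1]]], x[[pairs[p, 2]]])
  }, numeric(1))

  sim_means <- matrix(NA_real_, n_replicates, d)
  sim_sds <- matrix(NA_real_, n_replicates, d)
  sim_taus <- matrix(NA_real_, n_replicates, np)
  for (r in seq_len(n_replicates)) {
    rep_seed <- if (is.null(seed)) NULL else derive_seed(seed, r)
    s <- sample_population(model, n, seed = rep_seed)
    s <- as.data.frame(s)[, vars]
    sim_means[r, ] <- vapply(s, mean, numeric(1))
    sim_sds[r, ] <- vapply(s, stats::sd, numeric(1))
    sim_taus[r, ] <- vapply(seq_len(np), function(p) {
      kendall_tau_cpp(s[[pairs[p, 1]]], s[[pairs[p, 2]]])
    }, numeric(1))
  }

  marginal_table <- tibble::tibble(
    variable = vars,
    real_mean = vapply(x, mean, numeric(1)),
    real_sd = vapply(x, stats::sd, numeric(1)),
    sim_mean = colMeans(sim_means),
    sim_sd = colMeans(sim_sds)
  )
  ci <- apply(sim_taus, 2, quantile, probs = c(0.025, 0.975), names = FALSE)
  tau_table <- tibble::tibble(
    var1 = vars[pairs[, 1]],
    var2 = vars[pairs[, 2]],
    tau_real = tau_real,
    tau_sim_mean = colMeans(sim_taus),
    ci_lower = ci[1, ],
    ci_upper = ci[2, ],
    delta_tau = colMeans(sim_taus) - tau_real,
    outside_ci = tau_real < ci[1, ] | tau_real > ci[2, ]
  )
  structure(
    list(marginal_table = marginal_table, tau_table = tau_table,
         n_replicates = as.integer(n_replicates)),
    class = "gof_report"
  )
}

#' @export
print.gof_report <- function(x, ...) {
  cat("<gof_report>", x$n_replicates, "replicates\n")
  print(x$marginal_table)
  print(x$tau_table)
  invisible(x)
}

#' @export
tidy.gof_report <- function(x, ...) x$tau_table

#' @export
glance.gof_report <- function(x, ...) {
  tibble::tibble(
    n_replicates = x$n_replicates,
    n_pairs = nrow(x$tau_table),
    n_outside_ci = sum(x$tau_table$outside_ci),
    max_abs_delta_tau = max(abs(x$tau_table$delta_tau))
  )
}

#' Plot a goodness-of-fit report
#'
#' Real versus mean simulated Kendall tau per variable pair, with the
#' simulated 95% percentile interval.
#'
#' @param object A `gof_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gof_report <- function(object, ...) {
  tt <- object$tau_table
  tt$pair <- paste(tt$var1, tt$var2, sep = " : ")
  ggplot2::ggplot(tt, ggplot2::aes(x = .data$tau_real, y = .data$tau_sim_mean)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_lower, ymax = .data$ci_upper),
                           width = 0) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$outside_ci)) +
    ggplot2::labs(x = "real Kendall tau", y = "simulated Kendall tau (mean, 95% PI)",
                  colour = "outside PI") +
    ggplot2::theme_minimal()
}
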