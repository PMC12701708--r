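#' Parameters of a fractal Perlin-noise field
#'
#' Classic lattice gradient noise: seeded random unit gradients on integer
#' lattice nodes, quintic-smoothstep interpolation of the corner dot
#' products, and several octaves superimposed. `lacunarity` multiplies the
#' spatial frequency from one octave to the next; `persistence` multiplies
#' the amplitude. `base_frequency` is the number of lattice cells spanned by
#' the longest edge of the simulated volume, so structures keep their
#' physical size when the voxel resolution changes.
#'
#' @param seed Integer noise seed. Fields are pure functions of
#'   `(seed, params, shape)`.
#' @param octaves Number of octaves (>= 1).
#' @param lacunarity Frequency multiplier per octave (> 1).
#' @param persistence Amplitude multiplier per octave, in `(0, 1]`.
#' @param base_frequency Lattice cells along the longest volume edge.
#' @param voxel_mm Isotropic voxel size in mm.
#' @return An object of class `perlin_params`.
#' @export
perlin_params <- function(seed = 1L, octaves = 4L, lacunarity = 2,
                          persistence = 0.5, base_frequency = 8,
                          voxel_mm = 0.1) {
  if (!is_count(octaves) || octaves < 1) stop_bs("`octaves` must be >= 1")
  if (!is_scalar_num(lacunarity) || lacunarity <= 1) stop_bs("`lacunarity` must be > 1")
  if (!is_scalar_num(persistence) || persistence <= 0 || persistence > 1) {
    stop_bs("`persistence` must be in (0, 1]")
  }
  if (!is_scalar_num(base_frequency) || base_frequency <= 0) {
    stop_bs("`base_frequency` must be positive")
  }
  structure(
    list(seed = as.integer(seed), octaves = as.integer(octaves),
         lacunarity = lacunarity, persistence = persistence,
         base_frequency = base_frequency, voxel_mm = voxel_mm),
    class = "perlin_params"
  )
}

check_shape <- function(shape) {
  if (length(shape) != 3 || any(!is.finite(shape)) || any(shape < 1) ||
      any(shape != floor(shape))) {
    stop_bs("`shape` must be three positive voxel dimensions")
  }
  as.integer(shape)
}

# amplitude normalizer: geometric sum of octave amplitudes times the
# single-octave bound sqrt(3)/2
fractal_amplitude <- function(octaves, persistence) {
  sum(persistence^(0:(octaves - 1)))
}

# map a raw (signed) field into [0, 1) using the theoretical amplitude bound,
# NOT the per-block min/max: thresholds must be comparable across blocks and
# slabs. The upper end is kept strictly below 1 so a threshold of exactly 1
# always yields an empty structure mask.
rescale_field <- function(raw, octaves, persistence) {
  amp <- fractal_amplitude(octaves, persistence) * sqrt(3) / 2
  clamp(raw / (2 * amp) + 0.5, 0, 1 - 1e-9)
}

#' Generate Perlin and fractal noise fields
#'
#' `perlin_field()` evaluates a single octave; `fractal_field()` superimposes
#' `params$octaves` octaves with geometric frequency/amplitude progression
#' and renormalizes by the theoretical amplitude sum. Both return values in
#' `[0, 1)` when `rescale = TRUE` (the default) or the raw signed noise when
#' `rescale = FALSE`. Raw single-octave noise is exactly zero on lattice
#' nodes. Passing an `offset` (in voxels) evaluates a translated window of
#' the same infinite field, which is how phantom assembly generates one
#' z-slab at a time.
#'
#' @param params A [perlin_params()].
#' @param shape Integer voxel dimensions `c(nx, ny, nz)`.
#' @param offset Voxel offset of the window origin.
#' @param rescale Map values into `[0, 1)` using the theoretical amplitude
#'   bound.
#' @param long_edge Voxel count defining the noise scale (defaults to
#'   `max(shape)`); phantom slabs pass the full-volume edge so slabs tile.
#' @return A 3D numeric array of dimension `shape`.
#' @export
#' @examples
#' f <- fractal_field(perlin_params(seed = 3), shape = c(16, 16, 16))
#' range(f)
perlin_field <- function(params, shape, offset = c(0, 0, 0), rescale = TRUE,
                         long_edge = max(shape)) {
  stopifnot(inherits(params, "perlin_params"))
  shape <- check_shape(shape)
  scale <- params$base_frequency / long_edge
  raw <- perlin_grid_cpp(shape, as.numeric(offset), scale, params$seed)
  if (rescale) raw <- rescale_field(raw, 1L, params$persistence)
  array(raw, dim = shape)
}

#' @rdname perlin_field
#' @export
fractal_field <- function(params, shape, offset = c(0, 0, 0), rescale = TRUE,
                          long_edge = max(shape)) {
  stopifnot(inherits(params, "perlin_params"))
  shape <- check_shape(shape)
  scale <- params$base_frequency / long_edge
  raw <- fractal_grid_cpp(shape, as.numeric(offset), scale, params$octaves,
                          params$lacunarity, params$persistence, params$seed)
  if (rescale) raw <- rescale_field(raw, params$octaves, params$persistence)
  array(raw, dim = shape)
}

#' Threshold specification for tissue structures
#'
#' A voxel belongs to a structure when its noise value is at least the
#' effective threshold `scaling_factor * base_threshold` (clamped to
#' `[0, 1]`). A threshold of 1 creates no structures; a threshold of 0 fills
#' the whole volume. The scaling factor (SF) is the single dial used to tune
#' volumetric breast density: raising SF removes structure voxels and never
#' adds any, which is also how tissue involution is simulated over time.
#'
#' @param base_thresholds Numeric vector of per-block thresholds in `[0, 1]`.
#' @param scaling_factor Positive multiplier applied to all base thresholds.
#' @return An object of class `threshold_spec`.
#' @export
threshold_spec <- function(base_thresholds, scaling_factor = 1) {
  if (!is.numeric(base_thresholds) || length(base_thresholds) < 1 ||
      any(!is.finite(base_thresholds)) ||
      any(base_thresholds < 0 | base_thresholds > 1)) {
    stop_bs("`base_thresholds` must be values in [0, 1]")
  }
  if (!is_scalar_num(scaling_factor) || scaling_factor < 0) {
    stop_bs("`scaling_factor` must be non-negative")
  }
  structure(list(base_thresholds = base_thresholds,
                 scaling_factor = scaling_factor),
            class = "threshold_spec")
}

effective_thresholds <- function(spec) {
  clamp(spec$base_thresholds * spec$scaling_factor, 0, 1)
}

#' Threshold a noise field into a binary structure mask
#'
#' @param field A noise field in `[0, 1]` (from [fractal_field()]).
#' @param spec A [threshold_spec()]; its first base threshold is used.
#' @return A logical array of the same dimension: `TRUE` where structure.
#' @export
threshold_structures <- function(field, spec) {
  stopifnot(inherits(spec, "threshold_spec"))
  rng <- range(field)
  if (rng[1] < 0 || rng[2] > 1) stop_bs("`field` values must lie in [0, 1]")
  thr <- effective_thresholds(spec)[1]
  field >= thr
}

#' Default texture blocks of a breast phantom
#'
#' Two superimposed tissue blocks: a coarse block for the larger glandular
#' structures and a finer block for thin connective texture. Each block has
#' its own noise parameters and base threshold; a phantom-level seed offsets
#' every block seed so phantoms are independent across seeds but all blocks
#' of one phantom are reproducible.
#'
#' @param voxel_mm Voxel size forwarded to the block noise parameters.
#' @return Named list of blocks, each with `params` and `threshold`.
#' @export
default_blocks <- function(voxel_mm = 1) {
  list(
    glandular = list(
      params = perlin_params(seed = 101L, octaves = 4L, lacunarity = 2,
                             persistence = 0.55, base_frequency = 8,
                             voxel_mm = voxel_mm),
      threshold = 0.60
    ),
    connective = list(
      params = perlin_params(seed = 202L, octaves = 3L, lacunarity = 2.5,
                             persistence = 0.5, base_frequency = 20,
                             voxel_mm = voxel_mm),
      threshold = 0.62
    )
  )
}

#' Default scaling-factor levels for density calibration
#'
#' Five representative SF levels whose achieved densities span roughly
#' 1--25% VBD on the default texture blocks, bracketing the whole clinical
#' density range of the temporal models.
#'
#' @return Numeric vector of five SF levels.
#' @export
default_sf_levels <- function() c(0.95, 0.985, 1.02, 1.055, 1.09)

#' Calibrate the threshold scaling factor against achieved density
#'
#' For each scaling factor (SF) level, builds `n_phantoms` independent
#' phantoms (new seed each) and records the mean and SD of the achieved
#' volumetric breast density (VBD%). A monotone decay curve
#' `log(vbd) = c0 + c1 SF + c2 SF^2` is then least-squares fitted to the
#' per-level means, giving an invertible SF -> VBD% map. The quadratic
#' log-linear form follows from the thresholding mechanism: the structure
#' fraction is the upper tail of an approximately Gaussian noise field, so
#' its log falls off quadratically in the threshold. If the fitted quadratic
#' is not monotone over the calibrated SF range, the pure exponential
#' (`c2 = 0`) is used instead.
#'
#' @param spec A [phantom_spec()] describing the phantom grid, outline
#'   volume and texture blocks.
#' @param sf_levels Numeric vector of at least two SF levels.
#' @param n_phantoms Phantoms per level.
#' @param seed Integer seed; phantom seeds are derived from it.
#' @return A `density_calibration` with `levels` (tibble: sf, mean_vbd,
#'   sd_vbd, n), the fitted curve coefficients and the calibrated ranges.
#' @export
calibrate_density <- function(spec = phantom_spec(),
                              sf_levels = default_sf_levels(),
                              n_phantoms = 10, seed = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (length(sf_levels) < 2) stop_bs("need at least two SF levels to calibrate")
  if (!is_count(n_phantoms) || n_phantoms < 1) stop_bs("`n_phantoms` must be >= 1")
  sf_levels <- sort(as.numeric(sf_levels))

  vbd <- matrix(NA_real_, n_phantoms, length(sf_levels))
  for (li in seq_along(sf_levels)) {
    for (pi in seq_len(n_phantoms)) {
      ph <- build_phantom(spec, sf = sf_levels[li],
                          seed = derive_seed(seed, (li - 1) * n_phantoms + pi))
      vbd[pi, li] <- compute_vbd(ph)
    }
  }
  levels <- tibble::tibble(
    sf = sf_levels,
    mean_vbd = colMeans(vbd),
    sd_vbd = apply(vbd, 2, stats::sd),
    n = as.integer(n_phantoms)
  )
  if (any(diff(levels$mean_vbd) >= 0)) {
    stop_bs("mean VBD is not strictly decreasing in SF; cannot fit a ",
            "monotone curve. Levels: ",
            paste(sprintf("SF %.3g -> %.2f%%", levels$sf, levels$mean_vbd),
                  collapse = ", "))
  }
  if (any(levels$mean_vbd <= 0)) stop_bs("achieved VBD must be positive at every level")

  # log-quadratic decay; fall back to log-linear if the quadratic is not
  # monotone over the calibrated range (needs >= 3 levels for the quadratic)
  curve <- NULL
  if (nrow(levels) >= 3) {
    fit2 <- lm(log(mean_vbd) ~ sf + I(sf^2), data = levels)
    cf <- coef(fit2)
    slope_ends <- cf[[2]] + 2 * cf[[3]] * range(levels$sf)
    if (all(is.finite(cf)) && all(slope_ends < 0)) {
      curve <- list(c0 = cf[[1]], c1 = cf[[2]], c2 = cf[[3]])
    }
  }
  if (is.null(curve)) {
    fit1 <- lm(log(mean_vbd) ~ sf, data = levels)
    cf <- coef(fit1)
    if (cf[[2]] >= 0) stop_bs("fitted calibration curve is not decreasing")
    curve <- list(c0 = cf[[1]], c1 = cf[[2]], c2 = 0)
  }

  structure(
    list(levels = levels, curve = curve,
         sf_range = range(levels$sf),
         vbd_range = range(levels$mean_vbd),
         spec = spec, seed = as.integer(seed)),
    class = "density_calibration"
  )
}

predict_vbd <- function(cal, sf) {
  exp(cal$curve$c0 + cal$curve$c1 * sf + cal$curve$c2 * sf^2)
}

#' @export
print.density_calibration <- function(x, ...) {
  cat("<density_calibration>", nrow(x$levels), "SF levels, VBD",
      sprintf("%.1f-%.1f%%", x$vbd_range[1], x$vbd_range[2]), "\n")
  print(x$levels)
  invisible(x)
}

#' @export
tidy.density_calibration <- function(x, ...) x$levels

#' @export
glance.density_calibration <- function(x, ...) {
  tibble::tibble(c0 = x$curve$c0, c1 = x$curve$c1, c2 = x$curve$c2,
                 sf_min = x$sf_range[1], sf_max = x$sf_range[2],
                 vbd_min = x$vbd_range[1], vbd_max = x$vbd_range[2],
                 mean_level_sd = mean(x$levels$sd_vbd))
}

#' Plot a density calibration
#'
#' Per-level mean +/- SD of achieved VBD% with the fitted inversion curve.
#'
#' @param object A `density_calibration`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.density_calibration <- function(object, ...) {
  lv <- object$levels
  grid <- tibble::tibble(sf = seq(object$sf_range[1], object$sf_range[2],
                                  length.out = 100))
  grid$vbd <- predict_vbd(object, grid$sf)
  ggplot2::ggplot(lv, ggplot2::aes(x = .data$sf, y = .data$mean_vbd)) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$vbd),
                       colour = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_vbd - .data$sd_vbd,
                                        ymax = .data$mean_vbd + .data$sd_vbd),
                           width = 0.01) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "threshold scaling factor (SF)",
                  y = "volumetric breast density (%)") +
    ggplot2::theme_minimal()
}

#' Invert a density calibration
#'
#' Finds, by bisection on the fitted curve, the scaling factor whose expected
#' VBD% equals the target. No extrapolation: the target must lie inside the
#' calibrated VBD range.
#'
#' @param cal A `density_calibration`.
#' @param target_vbd Target density in percent.
#' @return The scaling factor (numeric scalar).
#' @export
sf_for_density <- function(cal, target_vbd) {
  stopifnot(inherits(cal, "density_calibration"))
  if (!is_scalar_num(target_vbd)) stop_bs("`target_vbd` must be a number")
  lo <- cal$vbd_range[1]
  hi <- cal$vbd_range[2]
  if (target_vbd < lo - 1e-9 || target_vbd > hi + 1e-9) {
    stop_bs(sprintf(
      "target VBD %.2f%% is outside the calibrated range [%.2f, %.2f]%%; %s",
      target_vbd, lo, hi, "recalibrate with wider SF levels"))
  }
  # the SF interval is widened marginally so level means sitting a fit
  # residual above/below the fitted endpoints still bracket a root; the
  # target itself is never extrapolated beyond the calibrated VBD range
  pad <- 0.05 * diff(cal$sf_range)
  uniroot(function(sf) predict_vbd(cal, sf) - target_vbd,
          interval = cal$sf_range + c(-pad, pad), tol = 1e-6,
          extendInt = "downX")$root
}

#' Save or load a density calibration as delimited text
#'
#' The per-level table is written as CSV; fitted curve coefficients and grid
#' provenance go into a JSON sidecar next to it.
#'
#' @param cal A `density_calibration`.
#' @param path CSV path (`<path>.json` holds the curve and spec summary).
#' @return `write_calibration()` returns `path` invisibly;
#'   `read_calibration()` returns the `density_calibration`.
#' @export
write_calibration <- function(cal, path) {
  stopifnot(inherits(cal, "density_calibration"))
  readr::write_csv(cal$levels, path)
  meta <- list(curve = cal$curve, sf_range = cal$sf_range,
               vbd_range = cal$vbd_range, seed = cal$seed,
               shape = cal$spec$shape, voxel_mm = cal$spec$voxel_mm,
               volume_cm3 = cal$spec$volume_cm3)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  levels <- readr::read_csv(path, col_types = readr::cols(
    sf = readr::col_double(), mean_vbd = readr::col_double(),
    sd_vbd = readr::col_double(), n = readr::col_integer()))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  spec <- phantom_spec(shape = meta$shape, voxel_mm = meta$voxel_mm,
                       volume_cm3 = meta$volume_cm3)
  structure(
    list(levels = tibble::as_tibble(levels),
         curve = as.list(meta$curve),
         sf_range = meta$sf_range, vbd_range = meta$vbd_range,
         spec = spec, seed = as.integer(meta$seed)),
    class = "density_calibration"
  )
}
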