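#' Lesion shape parameters
#'
#' An irregular soft-tissue mass is modeled as a sphere whose surface radius
#' is perturbed by low-frequency noise: `r(dir) = R * (1 + a * noise(dir))`,
#' with the noise evaluated on the unit direction sphere in a
#' size-normalized frame. Because the frame does not depend on the lesion
#' diameter, regrowing a lesion at a larger size preserves its margin shape.
#'
#' @param amplitude Relative radial perturbation amplitude `a`.
#' @param noise_frequency Spatial frequency of the margin noise on the unit
#'   sphere (higher = more, finer lobulations).
#' @param octaves,lacunarity,persistence Fractal parameters of the margin
#'   noise.
#' @param enhancement Multiplicative contrast factor applied to background
#'   glandular weights for heterogeneous lesions (methods 2 and 3); the
#'   enhanced weight is clamped at 1.
#' @param interior_frequency Base frequency of the added interior texture
#'   field (method 3), in cells across the lesion.
#' @return An object of class `lesion_params`.
#' @export
lesion_params <- function(amplitude = 0.2, noise_frequency = 1.5,
                          octaves = 3L, lacunarity = 2, persistence = 0.5,
                          enhancement = 1.5, interior_frequency = 4) {
  if (!is_scalar_num(amplitude) || amplitude < 0 || amplitude >= 1) {
    stop_bs("`amplitude` must be in [0, 1)")
  }
  if (!is_scalar_num(enhancement) || enhancement < 1) {
    stop_bs("`enhancement` must be >= 1")
  }
  structure(
    list(amplitude = amplitude, noise_frequency = noise_frequency,
         octaves = as.integer(octaves), lacunarity = lacunarity,
         persistence = persistence, enhancement = enhancement,
         interior_frequency = interior_frequency),
    class = "lesion_params"
  )
}

# normalized margin noise in [-1, 1] at unit directions
margin_noise <- function(dirs, params, seed) {
  amp <- sum(params$persistence^(0:(params$octaves - 1))) * sqrt(3) / 2
  raw <- fractal_points_cpp(
    dirs[, 1] * params$noise_frequency + 7.37,
    dirs[, 2] * params$noise_frequency + 11.91,
    dirs[, 3] * params$noise_frequency + 4.53,
    params$octaves, params$lacunarity, params$persistence, seed)
  clamp(raw / amp, -1, 1)
}

#' Generate a soft-tissue lesion
#'
#' Three synthesis methods: method 1 is a homogeneous mass (uniform
#' composition); method 2 marks the lesion as background-enhancing (existing
#' glandular weights inside the lesion are multiplied by the enhancement
#' factor at insertion time); method 3 additionally attaches an interior
#' fractal noise field that is mapped to graded mixture indices when the
#' lesion is stamped into a phantom. The margin is the noise-perturbed
#' sphere of [lesion_params()], rescaled so the largest grid-axis extent of
#' the voxelized shape matches the declared diameter.
#'
#' @param diameter_mm Lesion diameter (largest axis) in mm; must span at
#'   least 2 voxels at the build resolution.
#' @param method Synthesis method, 1, 2 or 3.
#' @param seed Integer seed; lesions are deterministic per
#'   `(seed, params, diameter)`.
#' @param voxel_mm Build resolution in mm.
#' @param params A [lesion_params()].
#' @return An object of class `breast_lesion` with the occupancy grid, the
#'   optional interior field, and shape metadata.
#' @export
#' @examples
#' les <- generate_lesion(5, method = 1, seed = 9, voxel_mm = 0.25)
#' lesion_volume_mm3(les)
generate_lesion <- function(diameter_mm, method = 1, seed = 1L,
                            voxel_mm = 0.1, params = lesion_params()) {
  stopifnot(inherits(params, "lesion_params"))
  if (!method %in% 1:3) stop_bs("`method` must be 1, 2 or 3")
  if (!is_scalar_num(diameter_mm) || diameter_mm / voxel_mm < 2) {
    stop_bs("diameter ", diameter_mm, " mm is below the resolvable size (2 voxels at ",
            voxel_mm, " mm)")
  }
  r_vox <- diameter_mm / voxel_mm / 2
  hw <- as.integer(ceiling(r_vox * (1 + params$amplitude))) + 2L
  n <- 2L * hw + 1L
  ctr <- hw + 1L

  ax <- seq_len(n) - ctr
  dx <- rep(ax, times = n * n)
  dy <- rep(rep(ax, each = n), times = n)
  dz <- rep(ax, each = n * n)
  rad <- sqrt(dx^2 + dy^2 + dz^2)
  rs <- pmax(rad, 1e-12)
  dirs <- cbind(dx / rs, dy / rs, dz / rs)
  pert <- if (params$amplitude > 0) margin_noise(dirs, params, seed) else 0
  radius_fun <- r_vox * (1 + params$amplitude * pert)

  axis_extent <- function(occ) {
    occ3 <- array(occ, dim = c(n, n, n))
    spans <- vapply(1:3, function(a) {
      pr <- apply(occ3, a, any)
      if (!any(pr)) return(0L)
      diff(range(which(pr))) + 1L
    }, integer(1))
    max(spans)
  }
  occ <- rad <= radius_fun
  ext <- axis_extent(occ)
  if (ext > 0) {
    scale <- (diameter_mm / voxel_mm) / ext
    occ <- rad <= radius_fun * scale
    # one refinement pass against voxelization bias
    ext2 <- axis_extent(occ)
    if (ext2 > 0) {
      scale <- scale * (diameter_mm / voxel_mm) / ext2
      occ <- rad <= radius_fun * scale
    }
  }
  occ <- array(occ, dim = c(n, n, n))
  if (!any(occ)) stop_bs("lesion occupancy is empty; diameter too small")

  interior <- NULL
  if (method == 3) {
    p <- perlin_params(seed = derive_seed(seed, 31L),
                       octaves = params$octaves,
                       lacunarity = params$lacunarity,
                       persistence = params$persistence,
                       base_frequency = params$interior_frequency,
                       voxel_mm = voxel_mm)
    interior <- fractal_field(p, c(n, n, n))
  }
  structure(
    list(occupancy = occ, interior = interior,
         diameter_mm = diameter_mm, method = as.integer(method),
         seed = as.integer(seed), voxel_mm = voxel_mm, params = params,
         center = rep(ctr, 3)),
    class = "breast_lesion"
  )
}

#' @export
print.breast_lesion <- function(x, ...) {
  cat(sprintf("<breast_lesion> %.1f mm, method %d, %d voxels @ %g mm, seed %d\n",
              x$diameter_mm, x$method, sum(x$occupancy), x$voxel_mm, x$seed))
  invisible(x)
}

#' Lesion volume
#'
#' @param lesion A `breast_lesion`.
#' @return Occupied volume in mm^3.
#' @export
lesion_volume_mm3 <- function(lesion) {
  stopifnot(inherits(lesion, "breast_lesion"))
  sum(lesion$occupancy) * lesion$voxel_mm^3
}

#' Regrow a lesion at a new diameter
#'
#' Regenerates the lesion with the identical seed and parameters at the new
#' size. Because the margin noise lives on the size-normalized direction
#' sphere, the margin shape is preserved while the volume scales roughly
#' cubically with diameter.
#'
#' @param lesion A `breast_lesion`.
#' @param new_diameter_mm Target diameter in mm.
#' @return A `breast_lesion`.
#' @export
regrow_lesion <- function(lesion, new_diameter_mm) {
  stopifnot(inherits(lesion, "breast_lesion"))
  generate_lesion(new_diameter_mm, method = lesion$method, seed = lesion$seed,
                  voxel_mm = lesion$voxel_mm, params = lesion$params)
}

#' Tumor growth model
#'
#' Linear increase of tumor diameter over time, anchored at the worked
#' clinical scenario: a 5 mm lesion with the cohort-mean doubling time of
#' 282 days reaches 10 mm after one doubling time and about 18 mm after two
#' years. Note the period `tdt` doubles the *diameter* in this model; a
#' strict volume-doubling variant (`d0 * 2^(t / (3 tdt))`, which doubles the
#' volume per period) is available via `mode = "volume"` in
#' [grown_diameter()].
#'
#' @param d0_mm Initial diameter in mm (> 0).
#' @param tdt_days Doubling time in days (> 0). Published cohort mean:
#'   282 days (range 46--749).
#' @return An object of class `growth_model`.
#' @export
growth_model <- function(d0_mm = 5, tdt_days = 282) {
  if (!is_scalar_num(d0_mm) || d0_mm <= 0) stop_bs("`d0_mm` must be positive")
  if (!is_scalar_num(tdt_days) || tdt_days <= 0) stop_bs("`tdt_days` must be positive")
  structure(list(d0 = d0_mm, tdt = tdt_days), class = "growth_model")
}

#' @export
print.growth_model <- function(x, ...) {
  cat(sprintf("<growth_model> d0 = %g mm, tdt = %g days\n", x$d0, x$tdt))
  invisible(x)
}

#' Tumor diameter after a growth interval
#'
#' @param g A [growth_model()].
#' @param t_days Elapsed time in days (>= 0); vectorized.
#' @param mode `"diameter"` (linear diameter, the default:
#'   `d = d0 (1 + t/tdt)`) or `"volume"` (strict volume doubling:
#'   `d = d0 * 2^(t / (3 tdt))`).
#' @return Diameter(s) in mm.
#' @export
#' @examples
#' grown_diameter(growth_model(5, 282), c(0, 282, 730))
grown_diameter <- function(g, t_days, mode = c("diameter", "volume")) {
  stopifnot(inherits(g, "growth_model"))
  mode <- match.arg(mode)
  if (any(!is.finite(t_days)) || any(t_days < 0)) {
    stop_bs("`t_days` must be non-negative")
  }
  switch(mode,
         diameter = g$d0 * (1 + t_days / g$tdt),
         volume = g$d0 * 2^(t_days / (3 * g$tdt)))
}

#' Save and load lesions
#'
#' Same raw + JSON sidecar convention as phantoms: the occupancy grid is
#' written as uint8 (0/1), metadata (diameter, method, seed, resolution,
#' shape parameters) goes into `<path>.json`. The method-3 interior texture
#' is deterministic in the stored seed and is regenerated on load.
#'
#' @param lesion A `breast_lesion`.
#' @param path Path of the `.raw` file.
#' @return `save_lesion()` returns `path` invisibly; `load_lesion()` the
#'   `breast_lesion`.
#' @export
save_lesion <- function(lesion, path) {
  stopifnot(inherits(lesion, "breast_lesion"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(lesion$occupancy), con)
  meta <- list(dims = dim(lesion$occupancy), diameter_mm = lesion$diameter_mm,
               method = lesion$method, seed = lesion$seed,
               voxel_mm = lesion$voxel_mm, params = unclass(lesion$params))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname save_lesion
#' @export
load_lesion <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  dims <- as.integer(meta$dims)
  expected <- prod(dims)
  actual <- file.size(path)
  if (is.na(actual) || actual != expected) {
    stop_bs("raw file size does not match sidecar dims")
  }
  con <- file(path, "rb")
  on.exit(close(con))
  occ <- array(as.logical(readBin(con, "raw", n = expected)), dim = dims)
  params <- do.call(lesion_params, meta$params)
  interior <- NULL
  if (meta$method == 3) {
    p <- perlin_params(seed = derive_seed(meta$seed, 31L),
                       octaves = params$octaves,
                       lacunarity = params$lacunarity,
                       persistence = params$persistence,
                       base_frequency = params$interior_frequency,
                       voxel_mm = meta$voxel_mm)
    interior <- fractal_field(p, dims)
  }
  structure(
    list(occupancy = occ, interior = interior,
         diameter_mm = meta$diameter_mm, method = as.integer(meta$method),
         seed = as.integer(meta$seed), voxel_mm = meta$voxel_mm,
         params = params, center = rep((dims[1] + 1) %/% 2, 3)),
    class = "breast_lesion"
  )
}
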