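#' Default material table of a voxel phantom
#'
#' Maps the small integer tissue indices stored in the voxel grid to
#' glandular weights `w_g` (1 = pure fibroglandular, 0 = pure adipose).
#' Index 0 is reserved for outside-breast air; indices 10--20 are a graded
#' adipose/glandular mixture ladder in steps of 0.1 used for heterogeneous
#' lesion compositions. Weights are configuration, not constants: downstream
#' x-ray simulation chains attach their own attenuation coefficients to the
#' same indices.
#'
#' @return Tibble with columns `index`, `tissue`, `w_g` (`w_g` is `NA` for
#'   air, which never enters density computations).
#' @export
default_material_table <- function() {
  tibble::tibble(
    index = c(0L, 1L, 2L, 3L, 10:20),
    tissue = c("air", "adipose", "glandular", "lesion",
               paste0("mixture_", seq(0, 100, by = 10), "pct")),
    w_g = c(NA, 0, 1, 1, seq(0, 1, by = 0.1))
  )
}

# index constants
IDX_AIR <- 0L
IDX_ADIPOSE <- 1L
IDX_GLANDULAR <- 2L
IDX_LESION <- 3L
IDX_MIX0 <- 10L

mixture_index <- function(w) IDX_MIX0 + as.integer(round(clamp(w, 0, 1) * 10))

#' Specify a breast phantom build
#'
#' Collects the grid shape, voxel size, target breast volume and texture
#' blocks used by [build_phantom()] and [calibrate_density()]. The default is
#' the desk-scale grid (220 x 120 x 60 voxels at 1 mm); the full-scale grid
#' of the simulation framework is 2200 x 1200 x 600 at 0.1 mm and covers the
#' same physical block, so noise structures keep their physical size across
#' resolutions.
#'
#' @param shape Grid dimensions in voxels `c(nx, ny, nz)`; x runs
#'   medial--lateral, y from the chest wall (y = 0 plane) to the nipple,
#'   z inferior--superior.
#' @param voxel_mm Isotropic voxel size in mm.
#' @param volume_cm3 Target breast volume.
#' @param blocks Texture blocks, see [default_blocks()].
#' @param material_table Index-to-weight map, see [default_material_table()].
#' @param slab_nz Z-slab thickness for tiled assembly; only one slab of
#'   texture is ever resident, so full-scale grids stay within memory.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(220, 120, 60), voxel_mm = 1,
                         volume_cm3 = 848, blocks = default_blocks(voxel_mm),
                         material_table = default_material_table(),
                         slab_nz = 32) {
  shape <- check_shape(shape)
  if (!is_scalar_num(voxel_mm) || voxel_mm <= 0) stop_bs("`voxel_mm` must be positive")
  if (!is_scalar_num(volume_cm3) || volume_cm3 <= 0) {
    stop_bs("`volume_cm3` must be positive")
  }
  stopifnot(is.list(blocks), length(blocks) >= 1)
  for (b in blocks) {
    stopifnot(inherits(b$params, "perlin_params"), is_scalar_num(b$threshold))
  }
  structure(
    list(shape = shape, voxel_mm = voxel_mm, volume_cm3 = volume_cm3,
         blocks = blocks, material_table = material_table,
         slab_nz = as.integer(slab_nz)),
    class = "phantom_spec"
  )
}

# ---- breast outline ----------------------------------------------------

# voxel count of the half-superellipsoid outline, computed analytically per
# (x, z) column so no voxel array is ever materialized (full-scale safe)
count_outline_voxels <- function(shape, voxel_mm, a, b, c_ax, e) {
  v <- voxel_mm
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  cx <- nx * v / 2
  cz <- nz * v / 2
  kx <- (abs((seq_len(nx) - 0.5) * v - cx) / a)^e
  kz <- (abs((seq_len(nz) - 0.5) * v - cz) / c_ax)^e
  rem <- 1 - outer(kx, kz, "+")
  pos <- rem > 0
  if (!any(pos)) return(0)
  ymax <- b * rem[pos]^(1 / e)
  sum(clamp(floor(ymax / v + 0.5), 0, ny))
}

#' Construct a breast outline mask of a target volume
#'
#' The breast region is a half-superellipsoid with a flat chest-wall face at
#' the y = 0 plane: `|x/a|^e + |y/b|^e + |z/c|^e <= 1` with `y >= 0`. For
#' volumes that fit as an ordinary half-ellipsoid (e = 2) the semi-axes are
#' scaled proportionally; larger volumes keep the maximal semi-axes and raise
#' the squareness exponent `e` instead (up to 8), bulging the shape toward
#' the block walls. Either way the free parameter is solved by bisection on
#' the exact voxel count until the discretized volume is within 1% of target.
#'
#' The outline is parametric: masks are materialized lazily (optionally one
#' z-slab at a time), so full-scale grids never require a whole-volume array.
#'
#' @param target_volume_cm3 Breast volume in cm^3 (> 0).
#' @param shape Grid dimensions in voxels.
#' @param voxel_mm Isotropic voxel size in mm.
#' @param tol Accepted relative deviation between the discretized and the
#'   target volume (default 1%). Very coarse grids (a few hundred breast
#'   voxels) quantize the achievable volumes; raise `tol` to accept the
#'   nearest one.
#' @return An object of class `breast_outline`.
#' @export
#' @examples
#' ol <- make_outline(400, shape = c(110, 60, 30), voxel_mm = 2)
#' outline_volume_cm3(ol)
make_outline <- function(target_volume_cm3, shape = c(220, 120, 60),
                         voxel_mm = 1, tol = 0.01) {
  shape <- check_shape(shape)
  if (!is_scalar_num(target_volume_cm3) || target_volume_cm3 <= 0) {
    stop_bs("`target_volume_cm3` must be positive")
  }
  v <- voxel_mm
  target_vox <- target_volume_cm3 * 1000 / v^3
  if (target_vox < 8) stop_bs("target volume is below the resolvable size")
  a_max <- shape[1] * v / 2 * 0.995
  b_max <- shape[2] * v * 0.995
  c_max <- shape[3] * v / 2 * 0.995

  count_se <- function(s, e) {
    count_outline_voxels(shape, v, s * a_max, s * b_max, s * c_max, e)
  }
  e <- 2
  if (count_se(1, 2) >= target_vox) {
    lo <- 1e-3; hi <- 1
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      if (count_se(mid, 2) < target_vox) lo <- mid else hi <- mid
    }
    s <- hi
  } else {
    if (count_se(1, 8) < target_vox) {
      stop_bs(sprintf(
        "target volume %.0f cm^3 does not fit the %dx%dx%d grid at %g mm",
        target_volume_cm3, shape[1], shape[2], shape[3], v))
    }
    s <- 1
    lo <- 2; hi <- 8
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      if (count_se(1, mid) < target_vox) lo <- mid else hi <- mid
    }
    e <- hi
  }
  n_vox <- count_se(s, e)
  achieved <- n_vox * v^3 / 1000
  if (abs(achieved - target_volume_cm3) / target_volume_cm3 > tol) {
    stop_bs(sprintf(
      "outline volume %.1f cm^3 deviates more than %.0f%% from target %.1f cm^3",
      achieved, 100 * tol, target_volume_cm3))
  }
  structure(
    list(shape = shape, voxel_mm = v,
         semi_axes = c(a = s * a_max, b = s * b_max, c = s * c_max),
         exponent = e,
         center = c(x = shape[1] * v / 2, y = 0, z = shape[3] * v / 2),
         n_voxels = n_vox, volume_cm3 = achieved,
         target_volume_cm3 = target_volume_cm3),
    class = "breast_outline"
  )
}

#' @export
print.breast_outline <- function(x, ...) {
  cat(sprintf("<breast_outline> %.1f cm^3 on %dx%dx%d @ %g mm (e = %.2f)\n",
              x$volume_cm3, x$shape[1], x$shape[2], x$shape[3],
              x$voxel_mm, x$exponent))
  invisible(x)
}

#' Materialize an outline mask
#'
#' @param outline A `breast_outline`.
#' @param z_idx Optional z indices to materialize (a slab); default all.
#' @return Logical array `nx x ny x length(z_idx)`, `TRUE` inside the breast.
#' @export
outline_mask <- function(outline, z_idx = NULL) {
  stopifnot(inherits(outline, "breast_outline"))
  v <- outline$voxel_mm
  shp <- outline$shape
  if (is.null(z_idx)) z_idx <- seq_len(shp[3])
  ax <- outline$semi_axes
  e <- outline$exponent
  kx <- (abs((seq_len(shp[1]) - 0.5) * v - outline$center["x"]) / ax["a"])^e
  ky <- (((seq_len(shp[2]) - 0.5) * v) / ax["b"])^e
  kz <- (abs((z_idx - 0.5) * v - outline$center["z"]) / ax["c"])^e
  kxy <- outer(kx, ky, "+")
  out <- array(FALSE, dim = c(shp[1], shp[2], length(z_idx)))
  for (k in seq_along(z_idx)) out[, , k] <- kxy + kz[k] <= 1
  out
}

#' @rdname outline_mask
#' @export
outline_volume_cm3 <- function(outline) outline$volume_cm3

#' Nipple position of an outline
#'
#' The voxel at the anterior apex of the breast: central medial--lateral and
#' inferior--superior coordinates, maximal chest-to-nipple coordinate.
#'
#' @param outline A `breast_outline`.
#' @return Integer voxel coordinates `c(x, y, z)`.
#' @export
nipple_position <- function(outline) {
  stopifnot(inherits(outline, "breast_outline"))
  v <- outline$voxel_mm
  ax <- outline$semi_axes
  e <- outline$exponent
  i <- as.integer(clamp(round(outline$center["x"] / v), 1, outline$shape[1]))
  k <- as.integer(clamp(round(outline$center["z"] / v), 1, outline$shape[3]))
  # anterior-most voxel of the center column, by the same inequality the
  # mask uses, so the nipple voxel is guaranteed inside the breast
  kx <- (abs((i - 0.5) * v - outline$center["x"]) / ax["a"])^e
  kz <- (abs((k - 0.5) * v - outline$center["z"]) / ax["c"])^e
  rem <- max(1 - kx - kz, 0)
  ymax <- ax["b"] * rem^(1 / e)
  c(x = i,
    y = as.integer(clamp(floor(ymax / v + 0.5), 1, outline$shape[2])),
    z = k)
}

# ---- phantom assembly --------------------------------------------------

block_seed <- function(phantom_seed, block_index, block_params_seed) {
  derive_seed(phantom_seed, 7919L * block_index + block_params_seed)
}

#' Assemble a voxel breast phantom
#'
#' Builds the phantom one z-slab at a time: for each slab, the outline mask
#' is materialized, each texture block's fractal field is evaluated on the
#' slab window (noise is a pure function of coordinates, so slabs tile
#' seamlessly), thresholded at `sf * base_threshold`, and the union of the
#' block structures is labeled glandular. Remaining inside-breast voxels are
#' adipose; outside is air. The same `seed` with a higher `sf` removes
#' structure voxels and never adds any -- the mechanism used to simulate
#' tissue involution on a fixed anatomy.
#'
#' @param spec A [phantom_spec()].
#' @param sf Threshold scaling factor.
#' @param seed Integer phantom seed.
#' @param outline Optional precomputed [make_outline()] result (otherwise
#'   derived from `spec$volume_cm3`).
#' @return An object of class `breast_phantom`: raw uint8 voxel array,
#'   material table, voxel size and provenance.
#' @export
build_phantom <- function(spec = phantom_spec(), sf = 1, seed = 1L,
                          outline = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!is_scalar_num(sf) || sf < 0) stop_bs("`sf` must be non-negative")
  if (is.null(outline)) {
    outline <- make_outline(spec$volume_cm3, spec$shape, spec$voxel_mm)
  }
  stopifnot(all(outline$shape == spec$shape))
  req <- c(IDX_AIR, IDX_ADIPOSE, IDX_GLANDULAR)
  if (!all(req %in% spec$material_table$index)) {
    stop_bs("material table must define indices ", paste(req, collapse = ", "))
  }
  shp <- spec$shape
  long_edge <- max(shp)
  voxels <- array(as.raw(0), dim = shp)
  thr <- vapply(spec$blocks, function(b) clamp(sf * b$threshold, 0, 1),
                numeric(1))
  raw_g <- as.raw(IDX_GLANDULAR)
  raw_a <- as.raw(IDX_ADIPOSE)
  z0 <- 1L
  while (z0 <= shp[3]) {
    z1 <- min(z0 + spec$slab_nz - 1L, shp[3])
    zi <- z0:z1
    slab_shape <- c(shp[1], shp[2], length(zi))
    inside <- outline_mask(outline, zi)
    struct <- array(FALSE, dim = slab_shape)
    for (bi in seq_along(spec$blocks)) {
      blk <- spec$blocks[[bi]]
      p <- blk$params
      p$seed <- block_seed(seed, bi, p$seed)
      field <- fractal_field(p, slab_shape, offset = c(0, 0, z0 - 1),
                             long_edge = long_edge)
      struct <- struct | (field >= thr[bi])
    }
    slab <- array(raw_a, dim = slab_shape)
    slab[struct] <- raw_g
    slab[!inside] <- as.raw(IDX_AIR)
    voxels[, , zi] <- slab
    z0 <- z1 + 1L
  }
  structure(
    list(voxels = voxels, material_table = spec$material_table,
         voxel_mm = spec$voxel_mm, shape = shp, outline = outline,
         provenance = list(seed = as.integer(seed), sf = sf,
                           thresholds = unname(thr),
                           insertions = list())),
    class = "breast_phantom"
  )
}

#' @export
print.breast_phantom <- function(x, ...) {
  cat(sprintf(
    "<breast_phantom> %dx%dx%d @ %g mm | breast %.1f cm^3 | VBD %.2f%% | seed %d, SF %.3g\n",
    x$shape[1], x$shape[2], x$shape[3], x$voxel_mm,
    x$outline$volume_cm3, compute_vbd(x),
    x$provenance$seed, x$provenance$sf))
  invisible(x)
}

#' Breast mask of a phantom
#'
#' @param phantom A `breast_phantom`.
#' @return Logical array, `TRUE` for inside-breast voxels (anything not air).
#' @export
breast_mask <- function(phantom) {
  stopifnot(inherits(phantom, "breast_phantom"))
  m <- phantom$voxels != as.raw(IDX_AIR)
  dim(m) <- phantom$shape
  m
}

# glandular-weight lookup vector indexed by tissue index + 1
weight_lookup <- function(material_table) {
  w <- rep(NA_real_, 256)
  w[material_table$index + 1] <- material_table$w_g
  w
}

#' Volumetric breast density of a phantom
#'
#' VBD% = 100 x (sum of glandular weights over inside-breast voxels) /
#' (number of inside-breast voxels). Air voxels enter neither sum. Processed
#' in chunks so full-scale phantoms need no integer copy of the whole grid.
#'
#' @param phantom A `breast_phantom`.
#' @return VBD in percent.
#' @export
compute_vbd <- function(phantom) {
  stopifnot(inherits(phantom, "breast_phantom"))
  w <- weight_lookup(phantom$material_table)
  total <- 0
  n_inside <- 0
  vox <- as.vector(phantom$voxels)
  chunk <- 4e6
  for (i0 in seq(1, length(vox), by = chunk)) {
    idx <- as.integer(vox[i0:min(i0 + chunk - 1, length(vox))])
    idx <- idx[idx != IDX_AIR]
    if (!length(idx)) next
    wg <- w[idx + 1]
    if (anyNA(wg)) {
      stop_bs("voxel index without material weight: ",
              paste(unique(idx[is.na(wg)]), collapse = ", "))
    }
    total <- total + sum(wg)
    n_inside <- n_inside + length(idx)
  }
  if (n_inside == 0) stop_bs("phantom has an empty breast mask")
  100 * total / n_inside
}

#' Rotate a phantom (repositioning between imaging sessions)
#'
#' Rigid rotation about the x, y and z axes with nearest-neighbor
#' resampling, so the output contains only voxel values present in the input
#' (plus air fill for regions rotated in from outside the grid). Angles can
#' be given explicitly or drawn uniformly from `angle_range` under `seed`,
#' emulating small positioning differences between screening visits.
#'
#' @param phantom A `breast_phantom`.
#' @param angles_deg Rotation angles in degrees about the x, y, z axes, or
#'   `NULL` to draw them from `angle_range`.
#' @param seed RNG seed for drawn angles.
#' @param angle_range Range (degrees) for random angles.
#' @param center `"centroid"` (breast-mask centroid, the default) or
#'   `"grid"` (geometric grid center, which makes 90-degree rotations of
#'   cubic grids exact voxel permutations).
#' @return A rotated `breast_phantom`.
#' @export
rotate_phantom <- function(phantom, angles_deg = NULL, seed = NULL,
                           angle_range = c(-5, 5),
                           center = c("centroid", "grid")) {
  stopifnot(inherits(phantom, "breast_phantom"))
  center <- match.arg(center)
  if (is.null(angles_deg)) {
    angles_deg <- with_seed(seed, runif(3, angle_range[1], angle_range[2]))
  }
  if (length(angles_deg) != 3 || any(!is.finite(angles_deg))) {
    stop_bs("`angles_deg` must be three finite angles")
  }
  if (all(angles_deg == 0)) return(phantom)
  shp <- phantom$shape
  th <- angles_deg * pi / 180
  rx <- matrix(c(1, 0, 0, 0, cos(th[1]), sin(th[1]), 0, -sin(th[1]), cos(th[1])), 3)
  ry <- matrix(c(cos(th[2]), 0, -sin(th[2]), 0, 1, 0, sin(th[2]), 0, cos(th[2])), 3)
  rz <- matrix(c(cos(th[3]), sin(th[3]), 0, -sin(th[3]), cos(th[3]), 0, 0, 0, 1), 3)
  rot <- rz %*% ry %*% rx

  ctr <- if (center == "grid") {
    (shp + 1) / 2
  } else {
    m <- breast_mask(phantom)
    idx <- which(m)
    k <- (idx - 1) %/% (shp[1] * shp[2])
    r <- (idx - 1) %% (shp[1] * shp[2])
    c(mean(r %% shp[1]) + 1, mean(r %/% shp[1]) + 1, mean(k) + 1)
  }

  out <- array(as.raw(IDX_AIR), dim = shp)
  rinv <- t(rot)
  xs <- seq_len(shp[1]) - ctr[1]
  ys <- seq_len(shp[2]) - ctr[2]
  gx <- rep(xs, times = shp[2])
  gy <- rep(ys, each = shp[1])
  for (k in seq_len(shp[3])) {
    dz <- k - ctr[3]
    sx <- round(rinv[1, 1] * gx + rinv[1, 2] * gy + rinv[1, 3] * dz + ctr[1])
    sy <- round(rinv[2, 1] * gx + rinv[2, 2] * gy + rinv[2, 3] * dz + ctr[2])
    sz <- round(rinv[3, 1] * gx + rinv[3, 2] * gy + rinv[3, 3] * dz + ctr[3])
    ok <- sx >= 1 & sx <= shp[1] & sy >= 1 & sy <= shp[2] &
      sz >= 1 & sz <= shp[3]
    lin <- (sz[ok] - 1) * shp[1] * shp[2] + (sy[ok] - 1) * shp[1] + sx[ok]
    slab <- rep(as.raw(IDX_AIR), shp[1] * shp[2])
    slab[ok] <- phantom$voxels[lin]
    out[, , k] <- slab
  }
  phantom$voxels <- out
  phantom$provenance$rotation_deg <- angles_deg
  phantom
}

# ---- serialization -----------------------------------------------------

#' Save and load phantoms
#'
#' The voxel grid is written as a raw little-endian unsigned 8-bit volume
#' (x fastest, then y, then z) with a JSON sidecar (`<path>.json`) holding
#' dimensions, voxel size, the material table and provenance. The round trip
#' is lossless; a mismatch between the sidecar dimensions and the raw file
#' size is an error.
#'
#' @param phantom A `breast_phantom`.
#' @param path Path of the `.raw` volume file.
#' @return `save_phantom()` returns `path` invisibly; `load_phantom()`
#'   returns the `breast_phantom`.
#' @export
save_phantom <- function(phantom, path) {
  stopifnot(inherits(phantom, "breast_phantom"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(phantom$voxels), con)
  meta <- list(
    dims = phantom$shape, voxel_mm = phantom$voxel_mm,
    material_table = phantom$material_table,
    outline = list(
      semi_axes = as.list(phantom$outline$semi_axes),
      exponent = phantom$outline$exponent,
      volume_cm3 = phantom$outline$volume_cm3,
      target_volume_cm3 = phantom$outline$target_volume_cm3
    ),
    provenance = phantom$provenance
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname save_phantom
#' @export
load_phantom <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  dims <- as.integer(meta$dims)
  expected <- prod(dims)
  actual <- file.size(path)
  if (is.na(actual) || actual != expected) {
    stop_bs("raw file size (", actual, " bytes) does not match sidecar dims (",
            paste(dims, collapse = "x"), " = ", expected, " bytes)")
  }
  con <- file(path, "rb")
  on.exit(close(con))
  vox <- readBin(con, what = "raw", n = expected)
  outline <- structure(
    list(shape = dims, voxel_mm = meta$voxel_mm,
         semi_axes = unlist(meta$outline$semi_axes),
         exponent = meta$outline$exponent,
         center = c(x = dims[1] * meta$voxel_mm / 2, y = 0,
                    z = dims[3] * meta$voxel_mm / 2),
         n_voxels = NA_real_,
         volume_cm3 = meta$outline$volume_cm3,
         target_volume_cm3 = meta$outline$target_volume_cm3),
    class = "breast_outline"
  )
  structure(
    list(voxels = array(vox, dim = dims),
         material_table = tibble::as_tibble(meta$material_table),
         voxel_mm = meta$voxel_mm, shape = dims, outline = outline,
         provenance = meta$provenance),
    class = "breast_phantom"
  )
}
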