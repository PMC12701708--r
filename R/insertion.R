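#' Lesion insertion policy
#'
#' Clinical lesion-location priors for the automatic insertion mode. The
#' published quadrant frequencies (upper-outer 58.5%, upper-inner 15.7%,
#' lower-outer 8.4%, lower-inner 9.9%) sum to 92.5% -- the residual
#' plausibly corresponds to central/retroareolar lesions outside the
#' four-quadrant scheme -- so they are renormalized over the four quadrants.
#' Within the sampled quadrant the insertion center is drawn with
#' probability proportional to the local glandular weight (plus a small
#' floor so fully adipose regions stay reachable), operationalizing the
#' assumed linear relationship between lesion position and breast density.
#'
#' @param quadrant_probs Named non-negative weights for `UO`, `UI`, `LO`,
#'   `LI` (renormalized internally).
#' @param interior_fraction Fraction of the breast volume retained by the
#'   interior mask that the insertion center must fall in (keeps lesions
#'   from being placed subcutaneously).
#' @param density_weighting Weight center sampling by local glandular
#'   weight.
#' @param floor Additive probability floor per voxel when density weighting
#'   is on.
#' @param max_retries Bounded number of quadrant resamples when a sampled
#'   quadrant has no admissible voxel.
#' @return An object of class `insertion_policy`.
#' @export
insertion_policy <- function(quadrant_probs = c(UO = 0.585, UI = 0.157,
                                                LO = 0.084, LI = 0.099),
                             interior_fraction = 0.90,
                             density_weighting = TRUE,
                             floor = 0.01,
                             max_retries = 10) {
  if (!all(c("UO", "UI", "LO", "LI") %in% names(quadrant_probs))) {
    stop_bs("`quadrant_probs` must name UO, UI, LO, LI")
  }
  quadrant_probs <- quadrant_probs[c("UO", "UI", "LO", "LI")]
  if (any(quadrant_probs < 0)) stop_bs("quadrant probabilities must be non-negative")
  if (sum(quadrant_probs) <= 0) stop_bs("at least one quadrant probability must be positive")
  if (!is_scalar_num(interior_fraction) || interior_fraction <= 0 ||
      interior_fraction > 1) {
    stop_bs("`interior_fraction` must be in (0, 1]")
  }
  structure(
    list(quadrant_probs = quadrant_probs,
         renormalized = quadrant_probs / sum(quadrant_probs),
         interior_fraction = interior_fraction,
         density_weighting = isTRUE(density_weighting),
         floor = floor, max_retries = as.integer(max_retries)),
    class = "insertion_policy"
  )
}

#' @export
print.insertion_policy <- function(x, ...) {
  cat("<insertion_policy>",
      paste(sprintf("%s %.3f", names(x$renormalized), x$renormalized),
            collapse = ", "),
      sprintf("| interior %.0f%%", 100 * x$interior_fraction), "\n")
  invisible(x)
}

#' Quadrant map of a breast phantom
#'
#' Partitions inside-breast voxels into the four clinical quadrants
#' (upper-outer, upper-inner, lower-outer, lower-inner) by two planes
#' through the nipple: a transverse plane separating superior from inferior
#' and a sagittal plane separating medial from lateral. `laterality` states
#' which side of the sagittal plane is lateral (outer): for a left breast
#' the lateral side is taken at larger x, for a right breast at smaller x,
#' so flipping the flag exchanges the outer and inner labels exactly.
#' Voxels exactly on a plane go to the inferior/non-positive side.
#'
#' @param phantom A `breast_phantom`.
#' @param nipple Voxel coordinates `c(x, y, z)` of the nipple; defaults to
#'   the outline apex.
#' @param laterality `"left"` or `"right"`.
#' @return Integer array over the grid: 1 = UO, 2 = UI, 3 = LO, 4 = LI,
#'   `NA` outside the breast; `levels` attribute carries the labels.
#' @export
quadrant_labels <- function(phantom, nipple = NULL,
                            laterality = c("left", "right")) {
  stopifnot(inherits(phantom, "breast_phantom"))
  laterality <- match.arg(laterality)
  if (is.null(nipple)) nipple <- nipple_position(phantom$outline)
  shp <- phantom$shape
  m <- breast_mask(phantom)
  nip <- as.integer(round(nipple))
  if (any(nip < 1) || any(nip > shp) || !m[nip[1], nip[2], nip[3]]) {
    stop_bs("nipple position must be an inside-breast voxel")
  }
  xi <- slice.index(m, 1)
  zi <- slice.index(m, 3)
  upper <- zi > nip[3]
  side_pos <- xi > nip[1]
  outer <- if (laterality == "left") side_pos else !side_pos
  q <- array(NA_integer_, dim = shp)
  q[m & upper & outer] <- 1L
  q[m & upper & !outer] <- 2L
  q[m & !upper & outer] <- 3L
  q[m & !upper & !outer] <- 4L
  attr(q, "levels") <- c("UO", "UI", "LO", "LI")
  q
}

#' Sample a quadrant from an insertion policy
#'
#' @param policy An [insertion_policy()].
#' @param seed Optional RNG seed.
#' @return One of `"UO"`, `"UI"`, `"LO"`, `"LI"`.
#' @export
sample_quadrant <- function(policy, seed = NULL) {
  stopifnot(inherits(policy, "insertion_policy"))
  with_seed(seed, {
    sample(names(policy$renormalized), 1, prob = policy$renormalized)
  })
}

#' Interior mask by uniform erosion
#'
#' Erodes the breast mask inward by ranking voxels on the exact Euclidean
#' distance transform and retaining the deepest `floor(fraction * N)`
#' voxels -- the largest retained volume not exceeding the requested
#' fraction. Ties on the cut shell are broken by voxel index, so the
#' erosion is deterministic. The result is always a subset of the input
#' mask; at the default fraction the retained voxels are strictly interior
#' (their whole 6-neighborhood lies inside the original mask).
#'
#' @param mask Logical 3D array.
#' @param fraction Volume fraction to retain, in (0, 1].
#' @return Logical array of the same dimension.
#' @export
interior_mask <- function(mask, fraction = 0.90) {
  if (!is.logical(mask) || length(dim(mask)) != 3) {
    stop_bs("`mask` must be a logical 3D array")
  }
  if (!is_scalar_num(fraction) || fraction <= 0 || fraction > 1) {
    stop_bs("`fraction` must be in (0, 1]")
  }
  n0 <- sum(mask)
  if (n0 == 0) stop_bs("`mask` is empty")
  d <- edt3d_cpp(as.vector(mask), dim(mask))
  k <- floor(fraction * n0)
  if (k < 1) stop_bs("fraction ", fraction, " yields an empty interior mask")
  # deepest k voxels; ties on the cut shell broken by voxel index (stable
  # radix order), so the erosion is deterministic and the retained volume is
  # the largest count <= fraction * original
  ord <- order(d, decreasing = TRUE)
  out <- logical(length(d))
  out[ord[seq_len(k)]] <- TRUE
  array(out, dim = dim(mask))
}

# admissible center voxels for a lesion: interior mask, restricted so the
# lesion's bounding radius stays inside the breast (uses the same EDT)
admissible_centers <- function(phantom, lesion, fraction) {
  m <- breast_mask(phantom)
  inner <- interior_mask(m, fraction)
  r_bound <- max_occupied_radius(lesion)
  if (r_bound > 0) {
    d <- edt3d_cpp(as.vector(m), dim(m))
    inner <- inner & array(d > r_bound, dim = dim(m))
  }
  inner
}

max_occupied_radius <- function(lesion) {
  occ <- lesion$occupancy
  if (!any(occ)) return(0)
  n <- dim(occ)[1]
  ax <- seq_len(n) - lesion$center[1]
  idx <- which(occ) - 1L
  i <- idx %% n + 1L
  j <- (idx %/% n) %% n + 1L
  k <- idx %/% (n * n) + 1L
  sqrt(max(ax[i]^2 + ax[j]^2 + ax[k]^2))
}

# write the lesion into the phantom voxel grid centered at `center`;
# the (air-padded) bounding box may hang over the grid edge as long as every
# occupied voxel stays inside the grid and the breast mask
stamp_lesion <- function(phantom, lesion, center) {
  shp <- phantom$shape
  occ <- lesion$occupancy
  ld <- dim(occ)
  off <- as.integer(round(center)) - lesion$center
  lo_g <- pmax(off + 1L, 1L)
  hi_g <- pmin(off + ld, shp)
  if (any(lo_g > hi_g)) {
    stop_bs("lesion lies entirely outside the phantom grid at this center")
  }
  lo_l <- lo_g - off
  hi_l <- hi_g - off
  occ_sub <- occ[lo_l[1]:hi_l[1], lo_l[2]:hi_l[2], lo_l[3]:hi_l[3]]
  dim(occ_sub) <- hi_l - lo_l + 1L
  if (sum(occ_sub) < sum(occ)) {
    stop_bs("lesion would extend beyond the phantom grid at this center")
  }
  w <- weight_lookup(phantom$material_table)
  sub <- phantom$voxels[lo_g[1]:hi_g[1], lo_g[2]:hi_g[2], lo_g[3]:hi_g[3]]
  dim(sub) <- dim(occ_sub)
  if (any(sub[occ_sub] == as.raw(IDX_AIR))) {
    stop_bs("lesion would extend outside the breast mask at this center")
  }
  if (lesion$method == 1) {
    sub[occ_sub] <- as.raw(IDX_LESION)
  } else {
    wg <- w[as.integer(sub[occ_sub]) + 1]
    wg <- pmin(1, wg * lesion$params$enhancement)
    if (lesion$method == 3) {
      int_sub <- lesion$interior[lo_l[1]:hi_l[1], lo_l[2]:hi_l[2],
                                 lo_l[3]:hi_l[3]]
      dim(int_sub) <- dim(occ_sub)
      wg <- pmax(wg, int_sub[occ_sub])
    }
    sub[occ_sub] <- as.raw(mixture_index(wg))
  }
  phantom$voxels[lo_g[1]:hi_g[1], lo_g[2]:hi_g[2], lo_g[3]:hi_g[3]] <- sub
  phantom
}

insertion_result <- function(phantom, center, quadrant, lesion, mode) {
  phantom$provenance$insertions <- c(
    phantom$provenance$insertions,
    list(list(center = as.integer(round(center)), quadrant = quadrant,
              mode = mode, diameter_mm = lesion$diameter_mm,
              method = lesion$method, lesion_seed = lesion$seed)))
  structure(
    list(phantom = phantom, center = as.integer(round(center)),
         quadrant = quadrant, n_voxels = sum(lesion$occupancy), mode = mode),
    class = "insertion_result"
  )
}

#' @export
print.insertion_result <- function(x, ...) {
  cat(sprintf("<insertion_result> %s at (%d, %d, %d), quadrant %s, %d voxels\n",
              x$mode, x$center[1], x$center[2], x$center[3],
              ifelse(is.na(x$quadrant), "-", x$quadrant), x$n_voxels))
  invisible(x)
}

#' Insert a lesion automatically
#'
#' Samples a quadrant from the policy, then draws the insertion center
#' within that quadrant's admissible region (interior mask, further eroded
#' by the lesion's bounding radius so the whole lesion stays inside the
#' breast) with probability proportional to the local glandular weight plus
#' the policy floor. If the sampled quadrant has no admissible voxel the
#' quadrant is resampled up to `policy$max_retries` times.
#'
#' @param phantom A `breast_phantom`.
#' @param lesion A `breast_lesion` built at the phantom's voxel size.
#' @param policy An [insertion_policy()].
#' @param nipple Optional nipple voxel coordinates (defaults to the outline
#'   apex).
#' @param seed Optional RNG seed.
#' @param laterality Breast laterality for the quadrant map.
#' @return An `insertion_result`: the modified phantom, the chosen center
#'   and quadrant, and the lesion voxel count.
#' @export
auto_insert <- function(phantom, lesion, policy = insertion_policy(),
                        nipple = NULL, seed = NULL, laterality = "left") {
  stopifnot(inherits(phantom, "breast_phantom"),
            inherits(lesion, "breast_lesion"))
  if (abs(lesion$voxel_mm - phantom$voxel_mm) > 1e-9) {
    stop_bs("lesion voxel size (", lesion$voxel_mm,
            " mm) differs from phantom voxel size (", phantom$voxel_mm, " mm)")
  }
  q <- quadrant_labels(phantom, nipple, laterality)
  adm <- admissible_centers(phantom, lesion, policy$interior_fraction)
  w <- weight_lookup(phantom$material_table)

  with_seed(seed, {
    for (try in seq_len(policy$max_retries + 1L)) {
      qlab <- sample(names(policy$renormalized), 1, prob = policy$renormalized)
      qi <- match(qlab, attr(q, "levels"))
      cand <- which(adm & !is.na(q) & q == qi)
      if (!length(cand)) next
      pw <- if (policy$density_weighting) {
        w[as.integer(phantom$voxels[cand]) + 1] + policy$floor
      } else {
        rep(1, length(cand))
      }
      if (sum(pw) <= 0) next
      pick <- if (length(cand) == 1) cand else sample(cand, 1, prob = pw)
      center <- linear_to_coord(pick, phantom$shape)
      ph2 <- stamp_lesion(phantom, lesion, center)
      return(insertion_result(ph2, center, qlab, lesion, "auto"))
    }
    stop_bs("no admissible insertion voxel found after ",
            policy$max_retries + 1, " quadrant draws")
  })
}

linear_to_coord <- function(idx, shp) {
  idx <- idx - 1L
  c(idx %% shp[1] + 1L,
    (idx %/% shp[1]) %% shp[2] + 1L,
    idx %/% (shp[1] * shp[2]) + 1L)
}

#' Insert a lesion at explicit coordinates
#'
#' The center must lie in the interior mask (the region that keeps lesions
#' from being subcutaneous); the lesion body must stay inside the breast
#' mask.
#'
#' @inheritParams auto_insert
#' @param center Voxel coordinates `c(x, y, z)` of the lesion center.
#' @param interior_fraction Interior-mask fraction for the center check.
#' @return An `insertion_result`.
#' @export
manual_insert <- function(phantom, lesion, center, interior_fraction = 0.90) {
  stopifnot(inherits(phantom, "breast_phantom"),
            inherits(lesion, "breast_lesion"))
  center <- as.integer(round(center))
  shp <- phantom$shape
  if (length(center) != 3 || any(center < 1) || any(center > shp)) {
    stop_bs("`center` must be voxel coordinates inside the grid")
  }
  inner <- interior_mask(breast_mask(phantom), interior_fraction)
  if (!inner[center[1], center[2], center[3]]) {
    stop_bs("center (", paste(center, collapse = ", "),
            ") is outside the interior mask (would be subcutaneous or outside)")
  }
  ph2 <- stamp_lesion(phantom, lesion, center)
  insertion_result(ph2, center, NA_character_, lesion, "manual")
}

#' Insert a lesion with partially fixed coordinates
#'
#' Semi-automatic mode: any subset of the x/y/z center coordinates is fixed
#' by the user (e.g. a fixed depth keeps z constant), the remaining axes are
#' drawn uniformly over the admissible voxels compatible with the fixed
#' coordinates and the optional per-axis ranges.
#'
#' @inheritParams auto_insert
#' @param fixed Named list of fixed voxel coordinates, e.g.
#'   `list(z = 30)` or `list(x = 100, y = 50)`.
#' @param ranges Optional named list of inclusive voxel ranges for the free
#'   axes, e.g. `list(y = c(20, 60))`.
#' @param interior_fraction Interior-mask fraction.
#' @return An `insertion_result`.
#' @export
semi_auto_insert <- function(phantom, lesion, fixed = list(), ranges = list(),
                             seed = NULL, interior_fraction = 0.90) {
  stopifnot(inherits(phantom, "breast_phantom"),
            inherits(lesion, "breast_lesion"))
  ax_names <- c("x", "y", "z")
  if (length(fixed) && !all(names(fixed) %in% ax_names)) {
    stop_bs("`fixed` names must be among x, y, z")
  }
  if (length(ranges) && !all(names(ranges) %in% ax_names)) {
    stop_bs("`ranges` names must be among x, y, z")
  }
  adm <- admissible_centers(phantom, lesion, interior_fraction)
  cand <- which(adm)
  if (!length(cand)) stop_bs("no admissible insertion voxel in the phantom")
  co <- vapply(cand, linear_to_coord, integer(3), shp = phantom$shape)
  keep <- rep(TRUE, length(cand))
  for (a in seq_along(ax_names)) {
    nm <- ax_names[a]
    if (!is.null(fixed[[nm]])) keep <- keep & co[a, ] == as.integer(round(fixed[[nm]]))
    if (!is.null(ranges[[nm]])) {
      keep <- keep & co[a, ] >= ranges[[nm]][1] & co[a, ] <= ranges[[nm]][2]
    }
  }
  cand <- cand[keep]
  if (!length(cand)) {
    stop_bs("no admissible voxel satisfies the fixed coordinates/ranges")
  }
  with_seed(seed, {
    pick <- if (length(cand) == 1) cand else sample(cand, 1)
    center <- linear_to_coord(pick, phantom$shape)
    ph2 <- stamp_lesion(phantom, lesion, center)
    insertion_result(ph2, center, NA_character_, lesion, "semi")
  })
}
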