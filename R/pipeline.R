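#' Orthographic ray-sum projection of a phantom
#'
#' Sums the glandular weights of the voxel grid along one axis (air
#' contributes zero) and min-max scales the result to 8-bit grayscale. This
#' is a quick structural preview of the phantom, not an x-ray simulation:
#' projection physics is the job of downstream virtual-clinical-trial
#' imaging chains.
#'
#' @param phantom A `breast_phantom`.
#' @param axis Projection axis: `"x"`, `"y"` or `"z"`.
#' @return An integer matrix in `[0, 255]` of class `raysum_image`.
#' @export
project_raysum <- function(phantom, axis = c("z", "y", "x")) {
  stopifnot(inherits(phantom, "breast_phantom"))
  axis <- match.arg(axis)
  ax <- match(axis, c("x", "y", "z"))
  w <- weight_lookup(phantom$material_table)
  w[IDX_AIR + 1] <- 0
  vals <- w[as.integer(phantom$voxels) + 1]
  dim(vals) <- phantom$shape
  img <- apply(vals, setdiff(1:3, ax), sum)
  rng <- range(img)
  scaled <- if (rng[2] > rng[1]) (img - rng[1]) / (rng[2] - rng[1]) else img * 0
  out <- matrix(as.integer(round(scaled * 255)), nrow(img), ncol(img))
  class(out) <- c("raysum_image", class(out))
  out
}

#' Write an 8-bit grayscale image as PGM
#'
#' Plain (ASCII, P2) portable graymap, readable by any image toolchain.
#'
#' @param img Integer matrix in `[0, 255]` (e.g. from [project_raysum()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pgm <- function(img, path) {
  m <- unclass(img)
  if (any(m < 0) || any(m > 255)) stop_bs("pixel values must be in [0, 255]")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(nrow(m), ncol(m)), "255"), con)
  # one image row per line; PGM is row-major, transpose from R's column-major
  apply(t(m), 1, function(row) writeLines(paste(row, collapse = " "), con))
  invisible(path)
}

#' @export
print.raysum_image <- function(x, ...) {
  cat("<raysum_image>", nrow(x), "x", ncol(x), "\n")
  invisible(x)
}

#' Plot a ray-sum preview
#'
#' @param object A `raysum_image`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.raysum_image <- function(object, ...) {
  m <- unclass(object)
  df <- expand.grid(i = seq_len(nrow(m)), j = seq_len(ncol(m)))
  df$value <- as.vector(m)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::theme(legend.position = "none")
}

#' Read a pipeline run configuration
#'
#' Run configurations are YAML with the keys of [run_pipeline()]'s `config`
#' argument; a configuration fully serializes a run, so re-running an
#' archived config reproduces the manifest metrics exactly.
#'
#' @param path YAML file path.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop_bs("config must be a YAML mapping")
  cfg
}

default_run_config <- function() {
  list(
    seed = 1L,
    n_women = 1L,
    ages = c(40, 57, 74),
    method = "A",
    shape = c(220, 120, 60),
    voxel_mm = 1,
    calibration = NULL,          # path to a saved calibration, or NULL
    sf_levels = NULL,            # inline calibration levels
    calibration_phantoms = 10L,
    lesion = NULL,               # list(d0_mm, tdt_days, method, insert)
    out_dir = NULL
  )
}

#' Run the end-to-end simulation pipeline
#'
#' Executes the configured stages for each virtual woman: temporal targets
#' (density, volume, tumor size) for the requested ages, density-calibrated
#' phantom construction at each age with a fixed per-woman noise seed
#' (so involution is a pure threshold change on one anatomy), optional
#' lesion growth and insertion, and phantom serialization. All randomness
#' flows from `config$seed` through named derived seeds recorded in the
#' manifest, so a rerun of the same config reproduces the same metrics.
#'
#' @param config Named list (see Details) or the path of a YAML file.
#'   Keys: `seed`, `n_women`, `ages`, `method`, `shape`, `voxel_mm`,
#'   `calibration` (path of a saved calibration) or `sf_levels` (inline
#'   calibration levels) with `calibration_phantoms`, optional `lesion`
#'   (`d0_mm`, `tdt_days`, `method`, `insert` = `"auto"`/`"semi"`), and
#'   `out_dir` (defaults to a temporary directory).
#' @return The run manifest tibble: one row per woman/age with the target
#'   and achieved VBD, volume, SF, tumor size, seeds and phantom file.
#'   Written alongside the phantoms as `manifest.csv`.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config) && length(config) == 1) {
    config <- read_run_config(config)
  }
  cfg <- utils::modifyList(default_run_config(), config)
  if (is.null(cfg$out_dir)) cfg$out_dir <- tempfile("breastsim_run_")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  # --- calibration stage
  spec <- phantom_spec(shape = cfg$shape, voxel_mm = cfg$voxel_mm)
  if (!is.null(cfg$calibration)) {
    cal <- read_calibration(cfg$calibration)
  } else if (!is.null(cfg$sf_levels)) {
    cal <- calibrate_density(spec, sf_levels = cfg$sf_levels,
                             n_phantoms = cfg$calibration_phantoms,
                             seed = derive_seed(cfg$seed, 5L))
    write_calibration(cal, file.path(cfg$out_dir, "calibration.csv"))
  } else {
    stop_bs("no density calibration configured: set `calibration` to a saved ",
            "calibration file or `sf_levels` to calibrate in-run ",
            "(see calibrate_density())")
  }

  growth <- if (!is.null(cfg$lesion)) {
    growth_model(cfg$lesion$d0_mm, cfg$lesion$tdt_days)
  }

  rows <- list()
  for (wi in seq_len(cfg$n_women)) {
    tl <- build_timeline(list(woman_id = wi), ages = cfg$ages,
                         method = cfg$method, calibration = cal,
                         growth = growth, seed = derive_seed(cfg$seed, wi))
    lesion0 <- if (!is.null(cfg$lesion)) {
      generate_lesion(cfg$lesion$d0_mm,
                      method = if (is.null(cfg$lesion$method)) 3 else cfg$lesion$method,
                      seed = derive_seed(cfg$seed, 900L + wi),
                      voxel_mm = cfg$voxel_mm)
    }
    for (ri in seq_len(nrow(tl))) {
      row <- tl[ri, ]
      outline <- make_outline(row$target_volume, spec$shape, spec$voxel_mm)
      ph <- build_phantom(spec, sf = row$sf, seed = row$phantom_seed,
                          outline = outline)
      quadrant <- NA_character_
      if (!is.null(cfg$lesion)) {
        les <- regrow_lesion(lesion0, row$tumor_mm)
        ins <- if (identical(cfg$lesion$insert, "semi")) {
          semi_auto_insert(ph, les, fixed = cfg$lesion$fixed %||% list(),
                           seed = derive_seed(cfg$seed, 7000L + 100L * wi + ri))
        } else {
          auto_insert(ph, les,
                      seed = derive_seed(cfg$seed, 7000L + 100L * wi + ri))
        }
        ph <- ins$phantom
        quadrant <- ins$quadrant
      }
      file <- file.path(cfg$out_dir,
                        sprintf("woman%03d_age%02d.raw", wi, round(row$age)))
      save_phantom(ph, file)
      rows[[length(rows) + 1]] <- tibble::tibble(
        woman_id = wi, age = row$age, method = cfg$method,
        target_vbd = row$target_vbd, achieved_vbd = compute_vbd(ph),
        target_volume = row$target_volume,
        achieved_volume = outline$volume_cm3,
        sf = row$sf, phantom_seed = row$phantom_seed,
        tumor_mm = if (!is.null(growth)) row$tumor_mm else NA_real_,
        quadrant = quadrant, file = basename(file)
      )
    }
  }
  manifest <- dplyr::bind_rows(rows)
  readr::write_csv(manifest, file.path(cfg$out_dir, "manifest.csv"))
  attr(manifest, "out_dir") <- cfg$out_dir
  manifest
}

`%||%` <- function(a, b) if (is.null(a)) b else a
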