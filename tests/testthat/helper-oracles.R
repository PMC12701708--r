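# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# O(n^2) Kendall tau-b by explicit pair counting
brute_tau <- function(x, y) {
  n <- length(x)
  conc <- 0; disc <- 0; tx <- 0; ty <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      dx <- sign(x[i] - x[j])
      dy <- sign(y[i] - y[j])
      if (dx == 0) tx <- tx + 1
      if (dy == 0) ty <- ty + 1
      if (dx == 0 || dy == 0) next
      if (dx == dy) conc <- conc + 1 else disc <- disc + 1
    }
  }
  n0 <- n * (n - 1) / 2
  (conc - disc) / sqrt((n0 - tx) * (n0 - ty))
}

# 26-connected single-component check by flood fill
is_connected <- function(occ) {
  idx <- which(occ)
  if (!length(idx)) return(FALSE)
  d <- dim(occ)
  visited <- array(FALSE, d)
  queue <- idx[1]
  visited[queue] <- TRUE
  offsets <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offsets <- offsets[rowSums(abs(offsets)) > 0, ]
  while (length(queue)) {
    cur <- queue[length(queue)]
    queue <- queue[-length(queue)]
    cur0 <- cur - 1L
    ci <- cur0 %% d[1] + 1L
    cj <- (cur0 %/% d[1]) %% d[2] + 1L
    ck <- cur0 %/% (d[1] * d[2]) + 1L
    for (r in seq_len(nrow(offsets))) {
      ni <- ci + offsets[r, 1]; nj <- cj + offsets[r, 2]; nk <- ck + offsets[r, 3]
      if (ni < 1 || ni > d[1] || nj < 1 || nj > d[2] || nk < 1 || nk > d[3]) next
      if (occ[ni, nj, nk] && !visited[ni, nj, nk]) {
        visited[ni, nj, nk] <- TRUE
        queue <- c(queue, (nk - 1L) * d[1] * d[2] + (nj - 1L) * d[1] + ni)
      }
    }
  }
  all(visited[occ])
}

# small phantom with hand-built voxels (air margin of 2 voxels all around);
# weights w are quantized onto the graded mixture indices
toy_phantom <- function(shape = c(40, 40, 40), w = 0.5, voxel_mm = 1) {
  mt <- default_material_table()
  vox <- array(as.raw(0), dim = shape)
  core <- lapply(shape, function(n) 3:(n - 2))
  warr <- array(w, dim = lengths(core))
  vox[core[[1]], core[[2]], core[[3]]] <- as.raw(10L + round(pmax(pmin(warr, 1), 0) * 10))
  outline <- make_outline(prod(shape - 4) * voxel_mm^3 / 1000 * 0.5,
                          shape = shape, voxel_mm = voxel_mm, tol = 0.3)
  structure(
    list(voxels = vox, material_table = mt, voxel_mm = voxel_mm,
         shape = as.integer(shape), outline = outline,
         provenance = list(seed = 0L, sf = 1, insertions = list())),
    class = "breast_phantom"
  )
}

# small desk phantom spec reused by several files (same physical block as
# the default grid, at 2 mm)
small_spec <- function(volume_cm3 = 400) {
  phantom_spec(shape = c(110, 60, 30), voxel_mm = 2, volume_cm3 = volume_cm3)
}

# radial extent of a lesion occupancy along sampled directions, in voxels
ray_radii <- function(occ, center, dirs, step = 0.25) {
  d <- dim(occ)
  vapply(seq_len(nrow(dirs)), function(r) {
    t <- 0
    repeat {
      t2 <- t + step
      p <- round(center + t2 * dirs[r, ])
      if (any(p < 1) || any(p > d) || !occ[p[1], p[2], p[3]]) return(t)
      t <- t2
    }
  }, numeric(1))
}

# glandular-weight array of a phantom (air = 0)
weights_of <- function(ph) {
  w <- rep(0, 256)
  w[ph$material_table$index + 1] <-
    ifelse(is.na(ph$material_table$w_g), 0, ph$material_table$w_g)
  arr <- w[as.integer(ph$voxels) + 1]
  dim(arr) <- ph$shape
  arr
}

# deterministic unit directions on the sphere (Fibonacci lattice)
fib_dirs <- function(m) {
  i <- seq_len(m) - 0.5
  z <- 1 - 2 * i / m
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}
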