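# Shared fixtures, built in code. All grids are small; anything expensive is
# memoised here so the suite builds it once.

# Solid axis-aligned cuboid mask: dims in cm, centred at `center`.
cuboid_mask <- function(dims, spacing = 0.1, center = c(0, 0, 0)) {
  half <- dims / 2
  n <- round(dims / spacing)
  origin <- center - half
  voxel_mask(origin, spacing, array(TRUE, dim = n))
}

# Digitized sphere (voxel-centre inclusion).
sphere_mask <- function(radius, spacing = 0.1, center = c(0, 0, 0)) {
  n <- rep(2L * ceiling(radius / spacing) + 2L, 3)
  origin <- center - n / 2 * spacing
  ax <- lapply(1:3, function(a) origin[a] + (seq_len(n[a]) - 0.5) * spacing -
                 center[a])
  occ <- outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`) <= radius^2
  voxel_mask(origin, spacing, occ)
}

# Water slab phantom: water for y <= surface_y, air above; generous x/z span.
water_slab <- function(surface_y, depth = 30, lateral = 20, spacing = 0.25,
                       air_above = 2) {
  origin <- c(-lateral / 2, surface_y - depth, -lateral / 2)
  n <- round(c(lateral, depth + air_above, lateral) / spacing)
  ys <- origin[2] + (seq_len(n[2]) - 0.5) * spacing
  rsp <- array(0.001, dim = n)
  rsp[, ys <= surface_y, ] <- 1
  density_grid(origin, spacing, rsp)
}

# Brute-force 10 um Riemann-sum water-equivalent depth: the independent
# oracle for the exact-traversal implementation.
wed_brute <- function(point, direction, density, surface_threshold = 0.2,
                      step = 0.001) {
  d <- direction / sqrt(sum(direction^2))
  dm <- dim(density$rsp)
  lo <- density$origin
  hi <- density$origin + dm * density$spacing
  t_exit <- Inf
  for (ax in 1:3) {
    if (abs(d[ax]) < 1e-14) next
    tt <- c((lo[ax] - point[ax]) / -d[ax], (hi[ax] - point[ax]) / -d[ax])
    t_exit <- min(t_exit, max(tt))
  }
  ts <- seq(step / 2, t_exit, by = step)
  pts <- cbind(point[1] - ts * d[1], point[2] - ts * d[2],
               point[3] - ts * d[3])
  i <- pmin(pmax(floor((pts[, 1] - lo[1]) / density$spacing[1]) + 1, 1), dm[1])
  j <- pmin(pmax(floor((pts[, 2] - lo[2]) / density$spacing[2]) + 1, 1), dm[2])
  k <- pmin(pmax(floor((pts[, 3] - lo[3]) / density$spacing[3]) + 1, 1), dm[3])
  inside <- pts[, 1] >= lo[1] & pts[, 1] < hi[1] &
    pts[, 2] >= lo[2] & pts[, 2] < hi[2] &
    pts[, 3] >= lo[3] & pts[, 3] < hi[3]
  rsp <- rep(0, length(ts))
  rsp[inside] <- density$rsp[cbind(i, j, k)[inside, , drop = FALSE]]
  above <- rsp > surface_threshold
  if (!any(above)) stop("oracle: no surface on ray")
  sum(rsp[seq_len(max(which(above)))]) * step
}

# Small hand-built factor set where every factor is exactly 1.
unit_factor_set <- function(calibration = 1) {
  t2 <- factor_table_2d(c(1, 50, 300), c(1, 5, 12),
                        matrix(1, 3, 3))
  t1d <- factor_table_1d(c(1, 20, 35), c(1, 1, 1))
  t1g <- factor_table_1d(c(0, 1, 12), c(1, 1, 1))
  factor_set(t2, t2, t1d, t1g, calibration = calibration)
}

# Memoised expensive fixtures (config, generated factor set).
.fx <- new.env(parent = emptyenv())
fx_config <- function() {
  if (is.null(.fx$cfg)) .fx$cfg <- toy_model_config()
  .fx$cfg
}
fx_factor_set <- function() {
  if (is.null(.fx$fs)) .fx$fs <- generate_factor_set(fx_config())
  .fx$fs
}
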