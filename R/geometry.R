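# Voxel-grid geometry: target masks, density grids, beam vectors, and the ray
# measurements (volume, BEV area, distal water-equivalent depth, air gap) that
# feed the cuboid MU model. All coordinates are continuous, in cm; voxel
# (i, j, k) occupies the half-open box origin + [(i-1)*s, i*s) on each axis.

#' Create a voxelized target mask
#'
#' A target (e.g. a PTV) represented as occupied voxels on a regular
#' axis-aligned grid.
#'
#' @param origin Numeric length-3: position of the corner of voxel (1,1,1), cm.
#' @param spacing Numeric length-3 (or scalar, recycled): voxel size per axis,
#'   cm; all > 0.
#' @param occupancy 3-D logical array of voxel occupancy.
#' @return A `voxel_mask` object.
#' @export
voxel_mask <- function(origin, spacing, occupancy) {
  spacing <- rep_len(as.numeric(spacing), 3L)
  origin <- as.numeric(origin)
  stopifnot(length(origin) == 3L, all(is.finite(origin)),
            all(is.finite(spacing)), all(spacing > 0))
  if (!is.array(occupancy) || length(dim(occupancy)) != 3L)
    stop("occupancy must be a 3-D array")
  storage.mode(occupancy) <- "logical"
  structure(list(origin = origin, spacing = spacing, occupancy = occupancy),
            class = "voxel_mask")
}

#' Create a relative-stopping-power density grid
#'
#' @param origin,spacing As in [voxel_mask()].
#' @param rsp 3-D numeric array of relative stopping power (water = 1), all
#'   values >= 0.
#' @return A `density_grid` object.
#' @export
density_grid <- function(origin, spacing, rsp) {
  spacing <- rep_len(as.numeric(spacing), 3L)
  origin <- as.numeric(origin)
  stopifnot(length(origin) == 3L, all(is.finite(origin)),
            all(is.finite(spacing)), all(spacing > 0))
  if (!is.array(rsp) || length(dim(rsp)) != 3L)
    stop("rsp must be a 3-D array")
  if (any(rsp < 0)) stop("rsp values must be >= 0")
  structure(list(origin = origin, spacing = spacing, rsp = rsp),
            class = "density_grid")
}

#' Uniform water phantom with an air layer above the entry surface
#'
#' Convenience constructor for tests and synthetic cases: a box of water
#' (rsp = 1) whose entry surface normal faces -`axis` direction can be placed
#' anywhere by `origin`.
#'
#' @param origin,spacing,dim Grid placement, voxel size, and voxel counts.
#' @param rsp_water Stopping power of the water region (default 1).
#' @return A `density_grid` filled uniformly with `rsp_water`.
#' @export
uniform_water_grid <- function(origin, spacing, dim, rsp_water = 1) {
  density_grid(origin, spacing, array(rsp_water, dim = dim))
}

#' Beam geometry: angles, isocenter and range-shifter configuration
#'
#' @param gantry_deg,couch_deg Gantry and couch angles, degrees.
#' @param isocenter Numeric length-3, cm.
#' @param range_shifted Logical; is the range shifter in the beam?
#' @param shifter_wet Water-equivalent thickness of the shifter, cm
#'   (default 4.1).
#' @param shifter_face_distance Distance of the shifter downstream face
#'   upstream of the isocenter along the beam axis, cm.
#' @return A `beam_geometry` object.
#' @export
beam_geometry <- function(gantry_deg, couch_deg = 0, isocenter = c(0, 0, 0),
                          range_shifted = FALSE, shifter_wet = 4.1,
                          shifter_face_distance = NA_real_) {
  stopifnot(is.finite(gantry_deg), is.finite(couch_deg),
            length(isocenter) == 3L, all(is.finite(isocenter)))
  if (isTRUE(range_shifted)) {
    if (!is.finite(shifter_wet) || shifter_wet <= 0)
      stop("shifter_wet must be > 0 for a range-shifted beam")
  }
  structure(list(gantry_deg = gantry_deg %% 360, couch_deg = couch_deg %% 360,
                 isocenter = as.numeric(isocenter),
                 range_shifted = isTRUE(range_shifted),
                 shifter_wet = shifter_wet,
                 shifter_face_distance = shifter_face_distance),
            class = "beam_geometry")
}

#' Beam direction unit vector from gantry and couch angles
#'
#' IEC 61217-style convention in a patient frame with +x patient-left,
#' +y anterior, +z superior. At gantry 0 the source is anterior and the beam
#' travels along (0, -1, 0); gantry rotates the source about +z
#' (gantry 90 gives beam (-1, 0, 0)); the couch rotates the patient about the
#' vertical (+y) axis. Parallel-beam geometry: every ray of the field shares
#' this direction (beam divergence is neglected, consistent with the large
#' effective source-axis distance of scanning systems).
#'
#' @param gantry_deg,couch_deg Angles in degrees (taken modulo 360).
#' @return Unit numeric length-3 vector pointing from source toward isocenter.
#' @export
beam_direction <- function(gantry_deg, couch_deg = 0) {
  stopifnot(is.finite(gantry_deg), is.finite(couch_deg))
  g <- (gantry_deg %% 360) * pi / 180
  c_ <- (couch_deg %% 360) * pi / 180
  # d = Ry(-couch) %*% Rz(-gantry) %*% c(0, -1, 0), written out
  d0 <- c(-sin(g), -cos(g), 0)
  d <- c(cos(c_) * d0[1] - sin(c_) * d0[3],
         d0[2],
         sin(c_) * d0[1] + cos(c_) * d0[3])
  d / sqrt(sum(d^2))
}

#' Target volume from an occupancy mask
#'
#' @param mask A [voxel_mask()].
#' @return Volume in cm^3 (occupied voxel count times voxel volume).
#' @export
mask_volume <- function(mask) {
  stopifnot(inherits(mask, "voxel_mask"))
  n <- sum(mask$occupancy)
  if (n == 0L) stop("degenerate target: mask has no occupied voxels")
  n * prod(mask$spacing)
}

# Orthonormal basis (u, v) spanning the plane orthogonal to d.
bev_basis <- function(d) {
  a <- if (abs(d[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- c(d[2] * a[3] - d[3] * a[2],
         d[3] * a[1] - d[1] * a[3],
         d[1] * a[2] - d[2] * a[1])
  u <- u / sqrt(sum(u^2))
  v <- c(d[2] * u[3] - d[3] * u[2],
         d[3] * u[1] - d[1] * u[3],
         d[1] * u[2] - d[2] * u[1])
  list(u = u, v = v)
}

# Corners of the grid bounding box of a mask/grid object.
grid_corners <- function(obj) {
  dm <- dim(obj[[3L]])
  lo <- obj$origin
  hi <- obj$origin + dm * obj$spacing
  as.matrix(expand.grid(x = c(lo[1], hi[1]), y = c(lo[2], hi[2]),
                        z = c(lo[3], hi[3])))
}

# Occupancy lookup for an n x 3 matrix of points; FALSE outside the grid.
mask_contains <- function(mask, pts) {
  dm <- dim(mask$occupancy)
  i <- floor((pts[, 1] - mask$origin[1]) / mask$spacing[1]) + 1
  j <- floor((pts[, 2] - mask$origin[2]) / mask$spacing[2]) + 1
  k <- floor((pts[, 3] - mask$origin[3]) / mask$spacing[3]) + 1
  ok <- i >= 1 & i <= dm[1] & j >= 1 & j <= dm[2] & k >= 1 & k <= dm[3]
  out <- logical(nrow(pts))
  if (any(ok)) {
    lin <- (k[ok] - 1L) * dm[1] * dm[2] + (j[ok] - 1L) * dm[1] + i[ok]
    out[ok] <- mask$occupancy[lin]
  }
  out
}

# Rasterize the beam's-eye-view plane over the mask bounding box and scan each
# parallel ray for mask occupancy. Returns per-ray hit flag and the parameter
# (t, along `direction`) of the first and last occupied sample, together with
# the ray origins and the sampling step. Origins sit on the plane through the
# bbox center; larger t is more downstream.
bev_ray_scan <- function(mask, direction, pixel_cm) {
  stopifnot(inherits(mask, "voxel_mask"))
  if (!isTRUE(pixel_cm > 0) || pixel_cm > min(mask$spacing) + 1e-12)
    stop("pixel_cm must satisfy 0 < pixel_cm <= min voxel spacing ",
         "(undersampling)")
  if (sum(mask$occupancy) == 0L) stop("degenerate target: empty mask")
  d <- direction / sqrt(sum(direction^2))
  bb <- bev_basis(d)
  corners <- grid_corners(mask)
  ctr <- colMeans(corners)
  rel <- sweep(corners, 2, ctr)
  a_rng <- range(rel %*% bb$u)
  b_rng <- range(rel %*% bb$v)
  t_rng <- range(rel %*% d)
  a <- seq(a_rng[1] - pixel_cm / 2, a_rng[2] + pixel_cm / 2, by = pixel_cm)
  b <- seq(b_rng[1] - pixel_cm / 2, b_rng[2] + pixel_cm / 2, by = pixel_cm)
  ab <- expand.grid(a = a, b = b)
  origins <- matrix(ctr, nrow = nrow(ab), ncol = 3, byrow = TRUE) +
    outer(ab$a, bb$u) + outer(ab$b, bb$v)
  step <- pixel_cm / 2
  ts <- seq(t_rng[1] - step, t_rng[2] + step, by = step)
  hit <- logical(nrow(origins))
  t_first <- rep(NA_real_, nrow(origins))
  t_last <- rep(NA_real_, nrow(origins))
  for (t in ts) {
    occ <- mask_contains(mask, origins + matrix(t * d, nrow(origins), 3,
                                                byrow = TRUE))
    t_first[occ & !hit] <- t
    t_last[occ] <- t
    hit <- hit | occ
  }
  list(origins = origins, direction = d, hit = hit,
       t_first = t_first, t_last = t_last, step = step, pixel_cm = pixel_cm)
}

#' Beam's-eye-view projected area of a target
#'
#' Area of the shadow of the occupied voxels on the plane orthogonal to the
#' beam direction, computed by casting one parallel ray per BEV pixel and
#' testing mask occupancy along it (sampling step is half the pixel size).
#' Invariant under translation of the mask along the beam axis.
#'
#' @param mask A [voxel_mask()].
#' @param direction Beam direction (unit 3-vector, see [beam_direction()]).
#' @param pixel_cm BEV raster resolution, cm; must not exceed the smallest
#'   voxel spacing.
#' @return Projected area in cm^2.
#' @export
bev_projected_area <- function(mask, direction, pixel_cm) {
  scan <- bev_ray_scan(mask, direction, pixel_cm)
  sum(scan$hit) * pixel_cm^2
}

# Exact traversal of one ray through a density grid, upstream from `point`.
# Returns the ordered voxel segments p(t) = point - t * d for t in [0, t_exit]:
# boundaries t (ascending, i.e. downstream -> upstream), per-segment rsp and
# length. NULL if the point lies outside the grid.
ray_segments_upstream <- function(point, d, density) {
  dm <- dim(density$rsp)
  lo <- density$origin
  hi <- density$origin + dm * density$spacing
  u <- -d  # upstream travel direction
  # slab intersection for t in [0, t_exit]
  t_exit <- Inf
  for (ax in 1:3) {
    if (abs(u[ax]) < 1e-14) {
      if (point[ax] < lo[ax] || point[ax] >= hi[ax]) return(NULL)
    } else {
      t1 <- (lo[ax] - point[ax]) / u[ax]
      t2 <- (hi[ax] - point[ax]) / u[ax]
      t_exit <- min(t_exit, max(t1, t2))
      if (min(t1, t2) > 1e-9) return(NULL)  # point outside slab
    }
  }
  if (!is.finite(t_exit) || t_exit <= 0) return(NULL)
  tb <- c(0, t_exit)
  for (ax in 1:3) {
    if (abs(u[ax]) < 1e-14) next
    ks <- seq(ceiling((min(point[ax], point[ax] + t_exit * u[ax]) - lo[ax]) /
                        density$spacing[ax]),
              floor((max(point[ax], point[ax] + t_exit * u[ax]) - lo[ax]) /
                      density$spacing[ax]))
    tc <- (lo[ax] + ks * density$spacing[ax] - point[ax]) / u[ax]
    tb <- c(tb, tc[tc > 0 & tc < t_exit])
  }
  tb <- sort(unique(tb))
  tm <- (tb[-1] + tb[-length(tb)]) / 2
  pts <- cbind(point[1] + tm * u[1], point[2] + tm * u[2], point[3] + tm * u[3])
  i <- pmin(pmax(floor((pts[, 1] - lo[1]) / density$spacing[1]) + 1, 1), dm[1])
  j <- pmin(pmax(floor((pts[, 2] - lo[2]) / density$spacing[2]) + 1, 1), dm[2])
  k <- pmin(pmax(floor((pts[, 3] - lo[3]) / density$spacing[3]) + 1, 1), dm[3])
  lin <- (k - 1L) * dm[1] * dm[2] + (j - 1L) * dm[1] + i
  list(t = tb, rsp = density$rsp[lin], len = diff(tb))
}

#' Water-equivalent depth of a point along a beam direction
#'
#' Line integral of relative stopping power from the patient surface to the
#' point, along the ray arriving at the point with the given direction. The
#' surface is the first crossing, traveling downstream from outside, where rsp
#' rises above `surface_threshold`; if the grid boundary itself is above
#' threshold, the boundary is taken as the surface. The integral is evaluated
#' by exact voxel-boundary traversal, so on a piecewise-constant grid it is
#' exact (no marching-step error).
#'
#' @param point Numeric length-3 position, cm; must lie inside the grid.
#' @param direction Beam direction unit vector.
#' @param density A [density_grid()].
#' @param surface_threshold rsp above which a voxel counts as patient
#'   (default 0.2, excludes air).
#' @return Water-equivalent depth in cm (>= 0).
#' @export
water_equivalent_depth <- function(point, direction, density,
                                   surface_threshold = 0.2) {
  stopifnot(inherits(density, "density_grid"))
  d <- direction / sqrt(sum(direction^2))
  seg <- ray_segments_upstream(as.numeric(point), d, density)
  if (is.null(seg)) stop("point lies outside the density grid")
  above <- seg$rsp > surface_threshold
  if (!any(above))
    stop("ray exits grid before finding a patient surface: ",
         "geometry misconfiguration")
  i_surf <- max(which(above))  # outermost above-threshold segment
  sum(seg$rsp[seq_len(i_surf)] * seg$len[seq_len(i_surf)])
}

# Upstream distance from `point` to the patient surface along -d (cm).
surface_distance_upstream <- function(point, d, density,
                                      surface_threshold = 0.2) {
  seg <- ray_segments_upstream(as.numeric(point), d, density)
  if (is.null(seg)) stop("central axis misses the density grid")
  above <- seg$rsp > surface_threshold
  if (!any(above))
    stop("ray exits grid before finding a patient surface: ",
         "geometry misconfiguration")
  seg$t[max(which(above)) + 1L]
}

# Refine the first/last occupied sample of a bev_ray_scan to the actual
# mask boundary by vectorized bisection (tolerance ~1e-3 cm). Brackets are
# [t_first - step, t_first] (entry) and [t_last, t_last + step] (exit); within
# a bracket there is a single occupancy transition.
bev_ray_refine <- function(mask, scan, iters = 12L) {
  idx <- which(scan$hit)
  d <- scan$direction
  O <- scan$origins[idx, , drop = FALSE]
  lo_in <- scan$t_first[idx] - scan$step  # unoccupied
  hi_in <- scan$t_first[idx]              # occupied
  lo_out <- scan$t_last[idx]              # occupied
  hi_out <- scan$t_last[idx] + scan$step  # unoccupied
  for (i in seq_len(iters)) {
    mid <- (lo_in + hi_in) / 2
    occ <- mask_contains(mask, O + mid * matrix(d, length(idx), 3,
                                                byrow = TRUE))
    hi_in[occ] <- mid[occ]
    lo_in[!occ] <- mid[!occ]
    mid <- (lo_out + hi_out) / 2
    occ <- mask_contains(mask, O + mid * matrix(d, length(idx), 3,
                                                byrow = TRUE))
    lo_out[occ] <- mid[occ]
    hi_out[!occ] <- mid[!occ]
  }
  list(idx = idx, t_entry = (lo_in + hi_in) / 2,
       t_exit = (lo_out + hi_out) / 2)
}

#' Average water-equivalent depth of the distal target surface
#'
#' For every BEV pixel whose ray intersects the mask, locates the
#' most-downstream mask crossing and evaluates [water_equivalent_depth()]
#' there. SFUD beam weights are concentrated at the distal edge of the target,
#' which is why the distal-surface average serves as the beam-range surrogate
#' of the MU model.
#'
#' @inheritParams bev_projected_area
#' @param density A [density_grid()] covering the mask and the upstream path
#'   to the patient surface.
#' @param surface_threshold Passed to [water_equivalent_depth()].
#' @return List with `mean_cm` and the `per_ray_cm` vector of distal depths.
#' @export
distal_surface_wed <- function(mask, density, direction, pixel_cm,
                               surface_threshold = 0.2) {
  stopifnot(inherits(density, "density_grid"))
  scan <- bev_ray_scan(mask, direction, pixel_cm)
  if (!any(scan$hit)) stop("no ray intersects the target mask")
  ref <- bev_ray_refine(mask, scan)
  d <- scan$direction
  wed <- vapply(seq_along(ref$idx), function(r) {
    p_distal <- scan$origins[ref$idx[r], ] + (ref$t_exit[r] - 1e-6) * d
    water_equivalent_depth(p_distal, d, density, surface_threshold) + 1e-6
  }, numeric(1))
  list(mean_cm = mean(wed), per_ray_cm = wed)
}

#' Air gap between the range-shifter face and the patient surface
#'
#' Distance along the central beam axis (the ray through the isocenter) from
#' the downstream face of the range shifter to the first patient-surface
#' crossing. Exact on a flat-surface phantom: the surface position comes from
#' the analytic voxel-boundary traversal, not from stepping.
#'
#' @param density A [density_grid()].
#' @param beam A [beam_geometry()] with `range_shifted = TRUE` and a finite
#'   `shifter_face_distance`.
#' @param mask Optional [voxel_mask()]; validated for non-emptiness only (the
#'   gap is a property of the axis and the patient surface).
#' @param surface_threshold As in [water_equivalent_depth()].
#' @return Air gap in cm (>= 0).
#' @export
air_gap <- function(density, beam, mask = NULL, surface_threshold = 0.2) {
  stopifnot(inherits(density, "density_grid"), inherits(beam, "beam_geometry"))
  if (!beam$range_shifted)
    stop("air gap is defined only for range-shifted beams")
  if (!is.finite(beam$shifter_face_distance))
    stop("beam has no shifter_face_distance")
  if (!is.null(mask) && sum(mask$occupancy) == 0L)
    stop("degenerate target: empty mask")
  d <- beam_direction(beam$gantry_deg, beam$couch_deg)
  t_surf <- surface_distance_upstream(beam$isocenter, d, density,
                                      surface_threshold)
  gap <- beam$shifter_face_distance - t_surf
  if (gap < -1e-9)
    stop("range-shifter face lies inside the patient (negative air gap)")
  max(gap, 0)
}
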