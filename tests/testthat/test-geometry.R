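# Geometry module: beam vectors, volume, BEV projection, water-equivalent
# depth ray tracing, air gap.

test_that("beam_direction follows the declared IEC-style convention", {
  expect_equal(beam_direction(0, 0), c(0, -1, 0))
  expect_equal(beam_direction(90, 0), c(-1, 0, 0))
  expect_equal(beam_direction(180, 0), c(0, 1, 0))
  expect_equal(beam_direction(360 + 90, 0), beam_direction(90, 0))
  # oracle: explicit rotation-matrix composition Ry(-couch) Rz(-gantry)
  rot <- function(g, c_) {
    Rz <- function(t) matrix(c(cos(t), -sin(t), 0, sin(t), cos(t), 0,
                               0, 0, 1), 3, byrow = TRUE)
    Ry <- function(t) matrix(c(cos(t), 0, sin(t), 0, 1, 0,
                               -sin(t), 0, cos(t)), 3, byrow = TRUE)
    as.numeric(Ry(-c_ * pi / 180) %*% Rz(-g * pi / 180) %*% c(0, -1, 0))
  }
  for (ang in list(c(37, 20), c(123, 340), c(270, 15)))
    expect_equal(beam_direction(ang[1], ang[2]), rot(ang[1], ang[2]),
                 tolerance = 1e-12)
  expect_equal(sqrt(sum(beam_direction(37, 20)^2)), 1)
})

test_that("mask_volume counts voxels and is additive over disjoint masks", {
  expect_equal(mask_volume(cuboid_mask(c(5, 5, 5), 0.1)), 125)
  one <- voxel_mask(c(0, 0, 0), 0.2, array(TRUE, c(1, 1, 1)))
  expect_equal(mask_volume(one), 0.008)
  sph <- sphere_mask(3, 0.1)
  expect_lt(abs(mask_volume(sph) - 4 / 3 * pi * 27) / (4 / 3 * pi * 27), 0.01)
  # exact additivity: split a mask into two disjoint halves
  occ <- sph$occupancy
  lo <- hi <- occ
  half <- dim(occ)[1] %/% 2
  lo[(half + 1):dim(occ)[1], , ] <- FALSE
  hi[1:half, , ] <- FALSE
  expect_identical(mask_volume(voxel_mask(sph$origin, sph$spacing, lo)) +
                     mask_volume(voxel_mask(sph$origin, sph$spacing, hi)),
                   mask_volume(sph))
  empty <- voxel_mask(c(0, 0, 0), 0.1, array(FALSE, c(2, 2, 2)))
  expect_error(mask_volume(empty), "degenerate")
})

test_that("bev_projected_area matches analytic shadows", {
  cube <- cuboid_mask(c(5, 5, 5), 0.1)
  expect_lt(abs(bev_projected_area(cube, c(0, -1, 0), 0.05) - 25) / 25,
            0.01)
  # 45 degrees in a face plane: shadow = 25 * sqrt(2)
  d45 <- c(1, -1, 0) / sqrt(2)
  expect_lt(abs(bev_projected_area(cube, d45, 0.05) - 25 * sqrt(2)) /
              (25 * sqrt(2)), 0.01)
  # sphere shadow: along a grid axis the digitized faces are flush and a
  # 0.1 cm grid suffices; obliquely the union-of-cubes silhouette protrudes
  # ~linearly in the voxel size, so a finer grid keeps it under 1%
  expect_lt(abs(bev_projected_area(sphere_mask(3, 0.1), c(0, -1, 0), 0.05) -
                  9 * pi) / (9 * pi), 0.01)
  sph <- sphere_mask(3, 0.025)
  d <- c(1, 2, -2) / 3
  expect_lt(abs(bev_projected_area(sph, d, 0.025) - 9 * pi) / (9 * pi),
            0.01)
  expect_error(bev_projected_area(cube, c(0, -1, 0), 0.2), "pixel_cm")
})

test_that("bev_projected_area is invariant under beam-axis translation and grid rotations", {
  cube <- cuboid_mask(c(4, 3, 2), 0.1)
  d <- c(1, 2, -2) / 3
  a0 <- bev_projected_area(cube, d, 0.05)
  shifted <- voxel_mask(cube$origin + 3 * d, cube$spacing, cube$occupancy)
  expect_lt(abs(bev_projected_area(shifted, d, 0.05) - a0) / a0, 0.005)
  # 90 degree grid rotation about z maps the grid to itself; rotate the
  # direction with it
  rot_occ <- aperm(cube$occupancy[dim(cube$occupancy)[1]:1, , ], c(2, 1, 3))
  rot_mask <- voxel_mask(cube$origin[c(2, 1, 3)], cube$spacing[c(2, 1, 3)],
                         rot_occ)
  d_rot <- c(d[2], -d[1], d[3])
  expect_lt(abs(bev_projected_area(rot_mask, d_rot, 0.05) - a0) / a0, 0.005)
})

test_that("water_equivalent_depth is exact on uniform and layered phantoms", {
  slab <- water_slab(10, depth = 30)
  d <- c(0, -1, 0)
  expect_equal(water_equivalent_depth(c(0, -10, 0), d, slab), 20)
  expect_equal(water_equivalent_depth(c(0, 10 - 1e-9, 0), d, slab), 0,
               tolerance = 1e-6)
  # layered: 5 cm of rsp 0.5 over water, point 10 cm deep geometrically
  lay <- water_slab(10, depth = 30)
  ys <- lay$origin[2] + (seq_len(dim(lay$rsp)[2]) - 0.5) * lay$spacing[2]
  lay$rsp[, ys <= 10 & ys > 5, ] <- 0.5
  p <- c(0, 0, 0)
  expect_equal(water_equivalent_depth(p, d, lay), 7.5)
  expect_equal(wed_brute(p, d, lay), 7.5, tolerance = 0.01)
  expect_error(water_equivalent_depth(c(0, 50, 0), d, slab), "outside")
})

test_that("water_equivalent_depth matches the 10 um brute-force oracle on random grids", {
  set.seed(42)
  for (i in 1:15) {
    den <- water_slab(10, depth = 25, lateral = 12, spacing = 0.25)
    ys <- den$origin[2] + (seq_len(dim(den$rsp)[2]) - 0.5) * den$spacing[2]
    brk <- sort(runif(4, -12, 10))
    vals <- runif(5, 0.3, 1.8)
    for (b in seq_along(brk)) den$rsp[, ys <= brk[b], ] <- vals[b]
    d <- c(runif(1, -0.25, 0.25), -1, runif(1, -0.25, 0.25))
    d <- d / sqrt(sum(d^2))
    p <- c(runif(1, -2, 2), runif(1, -10, 4), runif(1, -2, 2))
    expect_lt(abs(water_equivalent_depth(p, d, den) - wed_brute(p, d, den)),
              0.01)
  }
})

test_that("distal_surface_wed finds the distal face and tracks translation", {
  slab <- water_slab(0, depth = 35)
  d <- c(0, -1, 0)
  cube <- cuboid_mask(c(5, 5, 5), 0.25, center = c(0, -17.5, 0))
  r <- distal_surface_wed(cube, slab, d, 0.25)
  expect_equal(r$mean_cm, 20, tolerance = 0.02)
  expect_lt(diff(range(r$per_ray_cm)), 0.01)
  # lateral translation leaves the mean unchanged
  cube_lat <- cuboid_mask(c(5, 5, 5), 0.25, center = c(3, -17.5, 0))
  expect_equal(distal_surface_wed(cube_lat, slab, d, 0.25)$mean_cm, r$mean_cm,
               tolerance = 1e-6)
  # translating deeper increases the mean by the translation
  cube_deep <- cuboid_mask(c(5, 5, 5), 0.25, center = c(0, -19.5, 0))
  expect_equal(distal_surface_wed(cube_deep, slab, d, 0.25)$mean_cm - r$mean_cm,
               2, tolerance = 0.02)
})

test_that("distal_surface_wed mean matches the analytic spherical-cap average", {
  # sphere r = 2 centred 10 cm deep: distal surface depth(rho) =
  # 10 + sqrt(r^2 - rho^2); disc average = 10 + 2/3 r
  slab <- water_slab(0, depth = 25)
  sph <- sphere_mask(2, 0.1, center = c(0, -10, 0))
  r <- distal_surface_wed(sph, slab, c(0, -1, 0), 0.1)
  expect_lt(abs(r$mean_cm - (10 + 2 / 3 * 2)) / (10 + 4 / 3), 0.01)
})

test_that("air_gap measures the shifter-face-to-surface distance on the axis", {
  slab <- water_slab(25, depth = 30)  # surface at y = +25, iso at origin
  bm <- function(fd) beam_geometry(0, 0, c(0, 0, 0), range_shifted = TRUE,
                                   shifter_face_distance = fd)
  expect_equal(air_gap(slab, bm(26)), 1)
  expect_equal(air_gap(slab, bm(25)), 0)
  expect_error(air_gap(slab, bm(24)), "inside the patient")
  open_beam <- beam_geometry(0, 0, c(0, 0, 0), range_shifted = FALSE)
  expect_error(air_gap(slab, open_beam), "range-shifted")
  # oblique flat surface: gap equals the analytic ray-plane distance
  den <- water_slab(12, depth = 30, lateral = 30, spacing = 0.25)
  xs <- den$origin[1] + (seq_len(dim(den$rsp)[1]) - 0.5) * den$spacing[1]
  ys <- den$origin[2] + (seq_len(dim(den$rsp)[2]) - 0.5) * den$spacing[2]
  # surface plane y = 10 + x * tan(30 deg)
  for (i in seq_along(xs))
    den$rsp[i, ys > 10 + xs[i] * tan(pi / 6), ] <- 0.001
  g <- air_gap(den, bm(15))
  expect_equal(g, 5, tolerance = 0.15)  # surface at y = 10 on the axis
})
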