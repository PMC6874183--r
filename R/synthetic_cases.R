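# Synthetic ground-truth cases: voxelized targets in a water phantom with a
# flat entry surface orthogonal to the beam, plus the toy-TPS MU that a
# secondary check should reproduce. Cuboid "node" cases replay the factor
# tabulation conditions exactly; ellipsoid and random-blob cases probe the
# cuboid approximation on realistic shapes.

with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv()) else
    suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(code)
}

# Water phantom with entry surface orthogonal to the beam at depth 0:
# depth(p) = s0 + p . d, water where depth > 0, air (rsp 0.001) above.
# The grid is an axis-aligned box just covering the target bounding half-
# extents plus the upstream path to the surface.
make_phantom <- function(direction, s0, half_extents, spacing = 0.25,
                         margin = 2.5) {
  d <- direction / sqrt(sum(direction^2))
  t_up <- s0 + margin  # cover this far upstream of the isocenter
  lo <- hi <- numeric(3)
  for (ax in 1:3) {
    e <- half_extents[ax] + margin
    lo[ax] <- -e - t_up * max(d[ax], 0)
    hi[ax] <- e + t_up * max(-d[ax], 0)
  }
  lo <- floor(lo / spacing) * spacing
  hi <- ceiling(hi / spacing) * spacing
  dm <- pmax(round((hi - lo) / spacing), 1L)
  xs <- lo[1] + (seq_len(dm[1]) - 0.5) * spacing
  ys <- lo[2] + (seq_len(dm[2]) - 0.5) * spacing
  zs <- lo[3] + (seq_len(dm[3]) - 0.5) * spacing
  depth <- outer(outer(xs * d[1], ys * d[2], `+`), zs * d[3], `+`) + s0
  rsp <- array(ifelse(depth > 0, 1, 0.001), dim = dm)
  density_grid(lo, spacing, rsp)
}

# Voxelize a target shape centred on the isocenter. dims/radii in cm.
make_target_mask <- function(shape, size, spacing = 0.25, blob_amp = 0.12,
                             blob_pars = NULL) {
  half <- switch(shape,
                 cuboid = size / 2,
                 ellipsoid = size,
                 blob = size * (1 + blob_amp + 0.05))
  pad <- 2L
  lo <- -(ceiling(half / spacing) + pad) * spacing
  dm <- 2L * (ceiling(half / spacing) + pad)
  xs <- lo[1] + (seq_len(dm[1]) - 0.5) * spacing
  ys <- lo[2] + (seq_len(dm[2]) - 0.5) * spacing
  zs <- lo[3] + (seq_len(dm[3]) - 0.5) * spacing
  X <- array(xs, dm)
  Y <- array(rep(ys, each = dm[1]), dm)
  Z <- array(rep(zs, each = dm[1] * dm[2]), dm)
  occ <- switch(shape,
    cuboid = abs(X) < size[1] / 2 & abs(Y) < size[2] / 2 &
      abs(Z) < size[3] / 2,
    ellipsoid = (X / size[1])^2 + (Y / size[2])^2 + (Z / size[3])^2 <= 1,
    blob = {
      g <- (sin(blob_pars$f[1] * X + blob_pars$p[1]) +
              sin(blob_pars$f[2] * Y + blob_pars$p[2]) +
              sin(blob_pars$f[3] * Z + blob_pars$p[3])) / 3
      (X / size[1])^2 + (Y / size[2])^2 + (Z / size[3])^2 <=
        (1 + blob_amp * g)^2
    },
    stop("unknown shape: ", shape))
  voxel_mask(lo, spacing, occ)
}

#' Generate a complete synthetic treatment-beam case
#'
#' Builds a voxelized target of the requested shape in a uniform water
#' phantom whose flat entry surface is orthogonal to the beam, and computes
#' the ground-truth MU with the full per-column toy model (layer-by-layer
#' dose over the actual shape, not the cuboid shortcut). The only stochastic
#' element is the random-blob surface perturbation, driven by `seed`.
#'
#' @param case_spec List with `shape` ("cuboid", "ellipsoid" or "blob"),
#'   `size` (cuboid edge lengths, or ellipsoid/blob semi-axes, cm, in the
#'   patient frame), `center_depth_cm` (water-equivalent depth of the target
#'   centre), `gantry_deg`, `couch_deg`, `range_shifted`, `gap_cm` (nominal
#'   air gap for shifted beams), `prescribed_dose_cGy` (default 200) and
#'   `site_label`.
#' @param config A [toy_model_config()].
#' @param seed Integer seed (blob perturbation only).
#' @param spacing Voxel size of the mask and phantom grids, cm.
#' @return A `mu_case`: `mask`, `density`, `beam`, `prescribed_dose_cGy`,
#'   `mu_ground_truth`, `site_label`, `spec`.
#' @export
generate_case <- function(case_spec, config = toy_model_config(), seed = 1L,
                          spacing = 0.25) {
  cs <- case_spec
  stopifnot(!is.null(cs$shape), !is.null(cs$size),
            is.finite(cs$center_depth_cm))
  cs$prescribed_dose_cGy <- cs$prescribed_dose_cGy %||% 200
  cs$gantry_deg <- cs$gantry_deg %||% 0
  cs$couch_deg <- cs$couch_deg %||% 0
  cs$range_shifted <- isTRUE(cs$range_shifted)
  cs$site_label <- cs$site_label %||% "unspecified"
  d <- beam_direction(cs$gantry_deg, cs$couch_deg)
  blob_pars <- if (cs$shape == "blob")
    with_seed(seed, list(f = stats::runif(3, 0.8, 2.0),
                         p = stats::runif(3, 0, 2 * pi)))
  mask <- make_target_mask(cs$shape, cs$size, spacing,
                           blob_amp = cs$blob_amp %||% 0.12,
                           blob_pars = blob_pars)
  half <- dim(mask$occupancy) * mask$spacing / 2
  s0 <- cs$center_depth_cm
  # target must fit below the surface: most-upstream occupied voxel centre
  # (plus half a voxel diagonal) must stay under depth 0
  ijk <- which(mask$occupancy, arr.ind = TRUE)
  ctr <- sweep(sweep(ijk - 0.5, 2, mask$spacing, `*`), 2, mask$origin, `+`)
  up_extent <- max(-(ctr %*% d)) + sqrt(sum(mask$spacing^2)) / 2
  if (s0 - up_extent <= 0.1)
    stop("infeasible case: target protrudes through the phantom surface")
  density <- make_phantom(d, s0, half, spacing)
  gap <- if (cs$range_shifted) cs$gap_cm %||% 1 else NA_real_
  beam <- beam_geometry(cs$gantry_deg, cs$couch_deg, c(0, 0, 0),
                        range_shifted = cs$range_shifted,
                        shifter_wet = config$reference$shifter_wet_cm,
                        shifter_face_distance = if (cs$range_shifted)
                          s0 + gap else NA_real_)
  gt <- toy_tps_mu(mask, density, beam, cs$prescribed_dose_cGy, config)
  structure(list(mask = mask, density = density, beam = beam,
                 prescribed_dose_cGy = cs$prescribed_dose_cGy,
                 mu_ground_truth = gt$mu, site_label = cs$site_label,
                 spec = cs),
            class = "mu_case")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Cuboid case specs replaying the factor tabulation conditions: output-factor
# nodes at reference depth/gap, depth-factor nodes (125 cm^3 cube translated
# through water), air-gap nodes (cube centred at 7.5 cm). n >= 40 by default.
node_case_specs <- function(config = toy_model_config()) {
  ref <- config$reference
  specs <- list()
  add <- function(s) specs[[length(specs) + 1L]] <<- s
  of_nodes <- expand.grid(a = c(9, 25, 81, 169), w = c(2, 4, 6, 8))
  for (i in seq_len(nrow(of_nodes))) {
    a <- of_nodes$a[i]; w <- of_nodes$w[i]
    add(list(shape = "cuboid", size = c(sqrt(a), w, sqrt(a)),
             center_depth_cm = ref$depth_cm - w / 2,
             site_label = "of_node"))
  }
  for (i in c(2, 6, 11, 15)) {  # a few shifted output-factor nodes
    a <- of_nodes$a[i]; w <- of_nodes$w[i]
    add(list(shape = "cuboid", size = c(sqrt(a), w, sqrt(a)),
             center_depth_cm = ref$depth_cm - ref$shifter_wet_cm - w / 2,
             range_shifted = TRUE, gap_cm = ref$gap_cm,
             site_label = "of_node_shifted"))
  }
  for (r in seq(8, 30, by = 2))  # depth-factor nodes
    add(list(shape = "cuboid", size = c(5, 5, 5),
             center_depth_cm = r - 2.5, site_label = "df_node"))
  for (g in 1:8)  # air-gap nodes: cube centred at 7.5 cm depth
    add(list(shape = "cuboid", size = c(5, 5, 5), center_depth_cm = 7.5,
             range_shifted = TRUE, gap_cm = g, site_label = "agf_node"))
  specs
}

# Clinically styled non-cuboid specs across the four site archetypes.
shaped_case_specs <- function(n = 40, seed = 1L) {
  sites <- rep(c("pelvis", "brain", "lung", "head_neck"), length.out = n)
  with_seed(seed, lapply(seq_len(n), function(i) {
    site <- sites[i]
    switch(site,
      pelvis = list(shape = "ellipsoid", site_label = site,
                    size = stats::runif(3, 3.0, 4.5),
                    center_depth_cm = round(stats::runif(1, 15, 21), 2),
                    gantry_deg = sample(c(90, 270), 1)),
      brain = list(shape = if (i %% 2) "ellipsoid" else "blob",
                   site_label = site,
                   size = stats::runif(3, 2.0, 3.5),
                   center_depth_cm = round(stats::runif(1, 6.5, 10), 2),
                   gantry_deg = sample(c(0, 45, 315), 1),
                   range_shifted = TRUE,
                   gap_cm = round(stats::runif(1, 1, 4), 2)),
      lung = list(shape = "blob", site_label = site,
                  size = stats::runif(3, 2.5, 4.0),
                  center_depth_cm = round(stats::runif(1, 8, 14), 2),
                  gantry_deg = sample(c(0, 30, 90, 180, 270), 1),
                  couch_deg = sample(c(0, 15, 345), 1)),
      head_neck = list(shape = "blob", site_label = site,
                       size = stats::runif(3, 2.0, 3.0),
                       center_depth_cm = round(stats::runif(1, 5.5, 8), 2),
                       gantry_deg = sample(c(0, 60, 300), 1),
                       range_shifted = TRUE,
                       gap_cm = round(stats::runif(1, 1, 6), 2)))
  }))
}

#' Generate the standard synthetic case bundle
#'
#' Materializes cuboid node cases (the factor-tabulation conditions) and a
#' set of clinically styled ellipsoid/blob cases across four site labels,
#' mirroring the structure of a per-site MU verification study.
#'
#' @param config A [toy_model_config()].
#' @param seed Integer master seed; per-case seeds are derived from it.
#' @param n_shaped Number of non-cuboid cases (default 40).
#' @param include_nodes Include the cuboid node cases (default TRUE).
#' @return List of `mu_case` objects.
#' @export
generate_case_bundle <- function(config = toy_model_config(), seed = 1L,
                                 n_shaped = 40, include_nodes = TRUE) {
  specs <- c(if (include_nodes) node_case_specs(config),
             shaped_case_specs(n_shaped, seed = seed))
  lapply(seq_along(specs), function(i)
    generate_case(specs[[i]], config, seed = (seed * 1000L + i) %% 2147483647L))
}
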