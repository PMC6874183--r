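# Analytic toy beam model standing in for a commissioned TPS. It produces
# (a) self-consistent factor tables by replaying the tabulation experiments
# (cuboid sweeps in area/width at reference depth, a 125 cm^3 cube translated
# through water, an air-gap sweep at 7.5 cm depth) and (b) ground-truth MU for
# arbitrary voxelized targets by per-column SOBP flattening plus a lateral
# Gaussian spot-sum, so the cuboid factor method can be tested end to end.
#
# Construction note: the pristine peak is a range-invariant shape scaled by a
# per-range efficiency exp(-k (R - 20)), and the lateral sigma depends on
# field mode and air gap but not on energy. That makes the cuboid output
# exactly separable into OF(area, width) * DF(range) * AGF(gap) at the
# tabulation conditions -- the toy world is one in which the factor method is
# exact for cuboids, so end-to-end deviations isolate the cuboid
# approximation itself (target shape), not toy-model noise.

#' Configuration of the analytic toy beam model
#'
#' All lengths in cm. Defaults describe a generic clinical scanning beamline:
#' pristine peaks with ~0.25 cm distal falloff sigma, 0.3 cm energy-layer
#' spacing (kept close to the distal sigma so SOBP plateaus are ripple-free),
#' ~0.45 cm air spot sigma growing to ~1.1 cm behind a range shifter at a
#' 6 cm gap.
#'
#' @param peak_sigma_proximal,peak_sigma_distal Gaussian widths of the
#'   pristine peak on its proximal/distal side.
#' @param entrance_frac Entrance plateau dose as a fraction of peak.
#' @param entrance_slope Per-cm rise of the entrance plateau toward the peak.
#' @param entrance_cut,entrance_cut_width Center (upstream of the peak) and
#'   width of the sigmoid that fades the entrance term out under the peak.
#' @param efficiency_slope k in the per-range output efficiency
#'   exp(-k (R - 20)); sets the slope of the depth-factor curve.
#' @param layer_spacing Energy-layer (pullback) spacing of SOBPs.
#' @param depth_sample Plateau sampling step for the SOBP weight solve.
#' @param sigma_open Lateral spot sigma for open fields.
#' @param sigma_shift0,sigma_shift_gap_slope Lateral sigma behind the range
#'   shifter at zero gap, and its growth per cm of air gap (> 0: scattered
#'   spots diverge over the gap).
#' @param bev_pixel Raster resolution of the engine's beam's-eye-view lattice.
#' @param amplitude Global cGy/MU scale of the model.
#' @param of_area_axis,of_width_axis,df_range_axis,agf_gap_axis Node
#'   placement of the generated factor tables (areas up to 225 cm^2, widths
#'   to 10 cm, ranges 4-32 cm, gaps 0-10 cm). The area axis is near-geometric
#'   so that bilinear interpolation of the convex ~1/area output dependence
#'   stays well under 1% everywhere; table density is a supplier choice and
#'   the generated tables are deliberately dense.
#' @param reference Reference conditions shared with [factor_set()].
#' @param seed Integer seed for the only stochastic element (random-blob
#'   target generation).
#' @return A `toy_model_config` list.
#' @export
toy_model_config <- function(peak_sigma_proximal = 0.45,
                             peak_sigma_distal = 0.25,
                             entrance_frac = 0.35,
                             entrance_slope = 0.004,
                             entrance_cut = 1.0,
                             entrance_cut_width = 0.15,
                             efficiency_slope = 0.008,
                             layer_spacing = 0.3,
                             depth_sample = 0.05,
                             sigma_open = 0.45,
                             sigma_shift0 = 0.6,
                             sigma_shift_gap_slope = 0.08,
                             bev_pixel = 0.25,
                             amplitude = 10,
                             of_area_axis = sort(unique(c(
                               (2:15)^2,
                               round(exp(seq(log(4), log(225),
                                             length.out = 32)), 1)))),
                             of_width_axis = seq(1, 10, by = 0.5),
                             df_range_axis = seq(4, 32, by = 2),
                             agf_gap_axis = 0:10,
                             reference = list(depth_cm = 20, gap_cm = 1,
                                              shifter_wet_cm = 4.1),
                             seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(peak_sigma_proximal > 0, peak_sigma_distal > 0,
            layer_spacing > 0, depth_sample > 0, sigma_open > 0,
            sigma_shift0 > 0, sigma_shift_gap_slope > 0, bev_pixel > 0,
            amplitude > 0, entrance_frac >= 0)
  structure(cfg, class = "toy_model_config")
}

# Range-invariant pristine peak shape as a function of offset from the peak
# position (offset < 0 proximal). Entrance plateau + asymmetric Gaussian peak.
bragg_shape <- function(offset, config) {
  sig <- ifelse(offset < 0, config$peak_sigma_proximal,
                config$peak_sigma_distal)
  peak <- exp(-offset^2 / (2 * sig^2))
  ent <- config$entrance_frac * (1 - config$entrance_slope * offset) /
    (1 + exp((offset + config$entrance_cut) / config$entrance_cut_width))
  peak + ent
}

# Per-range output efficiency (cGy/MU scale of a pristine layer).
range_efficiency <- function(range_cm, config) {
  exp(-config$efficiency_slope * (range_cm - config$reference$depth_cm))
}

#' Pristine Bragg curve of the toy model
#'
#' @param range_cm Peak range in cm, within the clinical band 4-32 cm.
#' @param config A [toy_model_config()].
#' @return A `pristine_bragg` object: `range_cm`, `depth_axis` (cm) and
#'   `dose_per_mu` samples. The peak sits at `range_cm`; dose falls below 1%
#'   of the peak within 1.5 cm beyond it; the peak-to-entrance ratio
#'   exceeds 2.
#' @export
bragg_curve <- function(range_cm, config = toy_model_config()) {
  if (!is.finite(range_cm) || range_cm < 4 || range_cm > 32)
    stop("range_cm outside the supported clinical band [4, 32] cm")
  z <- seq(0, range_cm + 2.5, by = 0.02)
  dose <- config$amplitude * range_efficiency(range_cm, config) *
    bragg_shape(z - range_cm, config)
  structure(list(range_cm = range_cm, depth_axis = z, dose_per_mu = dose),
            class = "pristine_bragg")
}

# Non-negative layer weights (in shape units, deepest layer first) that
# flatten Sum_i u_i B0(s + i*Delta) to 1 on s in [-width, 0].
sobp_shape_weights <- function(width, config) {
  delta <- config$layer_spacing
  n <- floor(width / delta) + 2L  # one proximal margin layer
  offs <- (seq_len(n) - 1L) * delta
  s <- seq(-width, 0, by = config$depth_sample)
  M <- outer(s, offs, function(si, oi) bragg_shape(si + oi, config))
  fit <- nnls_fit(M, rep(1, length(s)))
  list(u = fit$x, offsets = offs, plateau_dose = fit$fitted, samples = s)
}

#' Flatten a spread-out Bragg peak
#'
#' Solves for non-negative pristine-layer weights (non-negative least
#' squares on a dense plateau sampling) so the summed depth dose is uniform
#' on `[distal_range_cm - width_cm, distal_range_cm]`. Deterministic.
#'
#' @param distal_range_cm Range of the deepest layer, cm.
#' @param width_cm SOBP width (modulation), cm; must be < `distal_range_cm`.
#' @param config A [toy_model_config()].
#' @return A `sobp_plan`: layer `ranges` (cm), MU `weights` per unit plateau
#'   dose, `plateau` interval, and achieved `flatness` (max relative
#'   deviation from the plateau mean, <= 0.02 by construction of the model).
#' @export
flatten_sobp <- function(distal_range_cm, width_cm,
                         config = toy_model_config()) {
  stopifnot(is.finite(distal_range_cm), is.finite(width_cm), width_cm > 0)
  if (width_cm >= distal_range_cm)
    stop("infeasible SOBP: width must be smaller than the distal range")
  sw <- sobp_shape_weights(width_cm, config)
  ranges <- distal_range_cm - sw$offsets
  if (any(ranges <= 0.5))
    stop("infeasible SOBP: proximal layers would need non-physical ranges")
  # MU weights: layer dose_per_mu carries amplitude * efficiency(R_i)
  weights <- sw$u / (config$amplitude * range_efficiency(ranges, config))
  mean_d <- mean(sw$plateau_dose)
  flat <- max(abs(sw$plateau_dose - mean_d)) / mean_d
  structure(list(ranges = ranges, weights = weights,
                 plateau = c(distal_range_cm - width_cm, distal_range_cm),
                 flatness = flat, shape_weights = sw$u,
                 offsets = sw$offsets),
            class = "sobp_plan")
}

# SOBP depth dose (shape units) at signed offset from the distal range.
sobp_offset_dose <- function(offset, u, offs, config) {
  as.numeric(outer(offset, offs, function(s, o) bragg_shape(s + o, config))
             %*% u)
}

# Lateral spot sigma (cm) by delivery mode and air gap.
lateral_sigma <- function(range_shifted, gap_cm, config) {
  if (!range_shifted) config$sigma_open
  else config$sigma_shift0 + config$sigma_shift_gap_slope * gap_cm
}

# Output (cGy/MU at the SOBP center) of an ideal cuboid field: square side
# sqrt(area), SOBP width `width`, effective distal range `r_eff`, lateral
# sigma `sigma`. Closed-form continuous limit of the voxel engine: the
# centre-of-field Gaussian spot-sum over a square of side L is
# erf(L / (2 sqrt(2) sigma))^2, which the engine's pixel lattice sum matches
# to ~1e-4 at the default resolution.
cuboid_output <- function(area, width, r_eff, sigma, config,
                          shape_cache = NULL) {
  L <- sqrt(area)
  erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1
  ksum <- erf(L / (2 * sqrt(2) * sigma))^2
  sw <- if (!is.null(shape_cache)) shape_cache(width) else
    sobp_shape_weights(width, config)
  d_center <- sobp_offset_dose(-width / 2, sw$u, sw$offsets, config)
  eff <- range_efficiency(r_eff - sw$offsets, config)
  total_weight <- area * sum(sw$u / (config$amplitude * eff))
  ksum * d_center / total_weight
}

# Memoising cache of sobp_shape_weights keyed by rounded width.
make_shape_cache <- function(config, round_to = 0.02) {
  env <- new.env(parent = emptyenv())
  function(width) {
    key <- sprintf("w%.2f", round(width / round_to) * round_to)
    if (is.null(env[[key]]))
      env[[key]] <- sobp_shape_weights(round(width / round_to) * round_to,
                                       config)
    env[[key]]
  }
}

#' Generate a self-consistent factor set from the toy beam model
#'
#' Replays the three tabulation experiments of the factor method against the
#' analytic model: output factors for cuboids spanning the clinical range of
#' BEV areas and SOBP widths at the reference depth (20 cm effective) and
#' reference gap; depth factors from a 25 cm^2 cuboid translated through
#' water (width 5 cm where feasible, 2 cm for the shallowest nodes, which in
#' this separable model yields the identical curve); air-gap factors from a
#' 125 cm^3 cube at 7.5 cm centre depth swept over gaps 0-10 cm.
#'
#' @param config A [toy_model_config()].
#' @return A validated [factor_set()].
#' @export
generate_factor_set <- function(config = toy_model_config()) {
  ref <- config$reference
  cache <- make_shape_cache(config)
  sig_open <- lateral_sigma(FALSE, 0, config)
  sig_sh_ref <- lateral_sigma(TRUE, ref$gap_cm, config)
  of_tab <- function(sigma) {
    v <- outer(config$of_area_axis, config$of_width_axis,
               Vectorize(function(a, w)
                 cuboid_output(a, w, ref$depth_cm, sigma, config, cache)))
    factor_table_2d(config$of_area_axis, config$of_width_axis, v)
  }
  of_open <- of_tab(sig_open)
  of_shifted <- of_tab(sig_sh_ref)
  df_vals <- vapply(config$df_range_axis, function(r) {
    w <- if (r >= 6.5) 5 else 2
    cuboid_output(25, w, r, sig_open, config, cache) /
      cuboid_output(25, w, ref$depth_cm, sig_open, config, cache)
  }, numeric(1))
  df <- factor_table_1d(config$df_range_axis, df_vals)
  # 125 cm^3 cube centred at 7.5 cm: chord 5-10 cm water, shifted delivery
  agf_ref <- cuboid_output(25, 5, 10 + ref$shifter_wet_cm,
                           lateral_sigma(TRUE, ref$gap_cm, config), config,
                           cache)
  agf_vals <- vapply(config$agf_gap_axis, function(g)
    cuboid_output(25, 5, 10 + ref$shifter_wet_cm,
                  lateral_sigma(TRUE, g, config), config, cache) / agf_ref,
    numeric(1))
  agf <- factor_table_1d(config$agf_gap_axis, agf_vals)
  factor_set(of_open, of_shifted, df, agf, reference = ref, calibration = 1)
}

# Ground-truth MU by full per-column simulation over the actual target shape:
# every BEV column is flattened on its own chord, the dose at the SOBP-centre
# point on the central axis is accumulated through the lateral Gaussian
# kernel, and MU is the summed column weight needed to reach the prescribed
# dose there.
toy_tps_mu <- function(mask, density, beam, prescribed_dose_cGy,
                       config = toy_model_config(), gap_cm = NULL,
                       surface_threshold = 0.2) {
  d <- beam_direction(beam$gantry_deg, beam$couch_deg)
  scan <- bev_ray_scan(mask, d, config$bev_pixel)
  if (!any(scan$hit)) stop("beam misses the target")
  refn <- bev_ray_refine(mask, scan)
  n <- length(refn$idx)
  O <- scan$origins[refn$idx, , drop = FALSE]
  wed_at <- function(tv) vapply(seq_len(n), function(r)
    water_equivalent_depth(O[r, ] + (tv[r] - 1e-6) * d, d, density,
                           surface_threshold), numeric(1))
  wed_dist <- wed_at(refn$t_exit)
  wed_prox <- wed_at(refn$t_entry + 2e-6)
  widths <- pmax(wed_dist - wed_prox, config$depth_sample)
  wet <- if (beam$range_shifted) beam$shifter_wet else 0
  r_eff <- wed_dist + wet
  if (beam$range_shifted && is.null(gap_cm))
    gap_cm <- air_gap(density, beam, mask, surface_threshold)
  sigma <- lateral_sigma(beam$range_shifted, if (is.null(gap_cm)) 0 else
    gap_cm, config)
  # BEV coordinates of each column relative to the central axis (isocenter)
  bb <- bev_basis(d)
  rel <- sweep(O, 2, beam$isocenter)
  a <- rel %*% bb$u
  b <- rel %*% bb$v
  r2 <- a^2 + b^2
  central <- which.min(r2)
  zstar <- r_eff[central] - widths[central] / 2
  cache <- make_shape_cache(config)
  pix <- config$bev_pixel
  kern <- pix^2 / (2 * pi * sigma^2) * exp(-r2 / (2 * sigma^2))
  dose_c <- 0
  total_weight <- 0
  for (r in seq_len(n)) {
    sw <- cache(widths[r])
    dose_c <- dose_c + kern[r] *
      sobp_offset_dose(zstar - r_eff[r], sw$u, sw$offsets, config)
    eff <- range_efficiency(r_eff[r] - sw$offsets, config)
    total_weight <- total_weight + pix^2 * sum(sw$u / (config$amplitude * eff))
  }
  output <- dose_c / total_weight  # cGy/MU at the SOBP-centre point
  list(mu = prescribed_dose_cGy / output, output_cgy_per_mu = output,
       sigma = sigma, eval_depth_eff = zstar,
       mean_distal_wed = mean(wed_dist))
}
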