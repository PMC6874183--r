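# The cuboid factor model: reduce a (target, beam) pair to an equivalent
# cuboid -- SOBP width = volume / BEV area, beam range = average distal
# water-equivalent depth (+ shifter WET when range-shifted) -- look up the
# output, depth and air-gap factors, and convert prescribed dose to MU.

#' Equivalent-cuboid summary of a target/beam pair
#'
#' The target is replaced by the cuboid with the same volume and BEV
#' projected area: its beam-axis extent (the SOBP width) is `volume / area`.
#' The beam range is the average distal-surface water-equivalent depth; for
#' range-shifted beams the shifter water-equivalent thickness is added.
#'
#' @param volume_cm3 Target volume, cm^3 (> 0).
#' @param bev_area_cm2 BEV projected area, cm^2 (> 0).
#' @param distal_wed_cm Mean distal-surface water-equivalent depth, cm (> 0).
#' @param beam A [beam_geometry()] (supplies `range_shifted`, `shifter_wet`).
#' @param gap_cm Air gap, cm; required when the beam is range-shifted.
#' @return A `cuboid_model`: `volume_cm3`, `bev_area_cm2`, `sobp_width_cm`,
#'   `distal_wed_cm`, `effective_range_cm`, `air_gap_cm`, `range_shifted`.
#' @export
cuboid_from_measurements <- function(volume_cm3, bev_area_cm2, distal_wed_cm,
                                     beam, gap_cm = NA_real_) {
  stopifnot(inherits(beam, "beam_geometry"))
  if (!isTRUE(volume_cm3 > 0) || !isTRUE(bev_area_cm2 > 0) ||
      !isTRUE(distal_wed_cm > 0))
    stop("volume, BEV area and distal WED must all be positive")
  width <- volume_cm3 / bev_area_cm2
  eff_range <- distal_wed_cm +
    if (beam$range_shifted) beam$shifter_wet else 0
  if (width >= eff_range)
    stop(sprintf(paste0("pathological target: equivalent SOBP width %.2f cm ",
                        "is not smaller than the effective range %.2f cm"),
                 width, eff_range))
  if (beam$range_shifted && !is.finite(gap_cm))
    stop("gap_cm is required for a range-shifted beam")
  structure(list(volume_cm3 = volume_cm3, bev_area_cm2 = bev_area_cm2,
                 sobp_width_cm = width, distal_wed_cm = distal_wed_cm,
                 effective_range_cm = eff_range,
                 air_gap_cm = if (beam$range_shifted) gap_cm else NA_real_,
                 range_shifted = beam$range_shifted),
            class = "cuboid_model")
}

#' Secondary MU from the factor model
#'
#' MU = prescribed dose / (OF(area, width) x DF(range) x AGF(gap) x
#' calibration), the conventional external-beam-style factorization. Clamp
#' warnings from table lookups are propagated in the result.
#'
#' @param prescribed_dose_cGy Point dose at the SOBP centre, cGy (> 0).
#' @param cuboid A [cuboid_from_measurements()] result.
#' @param set A [factor_set()].
#' @param multifield Set TRUE to tag a beam as multifield-optimized; such
#'   beams are refused -- the factor model is valid for SFUD optimization
#'   only and results would be poor for jointly optimized fields.
#' @return A `beam_mu_result`: `mu_calculated`, factor `components`,
#'   `warnings` (character vector, e.g. table clamping), and slots for
#'   `mu_tps` / `percent_diff` filled by [compare_mu()].
#' @export
compute_mu <- function(prescribed_dose_cGy, cuboid, set, multifield = FALSE) {
  stopifnot(inherits(cuboid, "cuboid_model"), inherits(set, "factor_set"))
  if (isTRUE(multifield))
    stop("beam is tagged multifield-optimized: the cuboid factor model ",
         "applies to SFUD beams only")
  if (!isTRUE(prescribed_dose_cGy > 0)) stop("prescribed dose must be > 0")
  of <- output_factor(set, cuboid$bev_area_cm2, cuboid$sobp_width_cm,
                      cuboid$range_shifted)
  df <- depth_factor(set, cuboid$effective_range_cm)
  agf <- air_gap_factor(set, if (cuboid$range_shifted) cuboid$air_gap_cm
                        else 0, cuboid$range_shifted)
  comps <- c(of = as.numeric(of), df = as.numeric(df), agf = as.numeric(agf),
             calibration = set$calibration)
  if (any(comps <= 0) || any(!is.finite(comps)))
    stop("corrupt factor tables: non-positive factor encountered")
  warns <- character(0)
  if (isTRUE(attr(of, "clamped")))
    warns <- c(warns, "output factor clamped to table boundary")
  if (isTRUE(attr(df, "clamped")))
    warns <- c(warns, "depth factor clamped to table boundary")
  if (isTRUE(attr(agf, "clamped")))
    warns <- c(warns, "air-gap factor clamped to table boundary")
  structure(list(mu_calculated = prescribed_dose_cGy / prod(comps),
                 mu_tps = NA_real_, percent_diff = NA_real_,
                 components = comps, cuboid = cuboid,
                 prescribed_dose_cGy = prescribed_dose_cGy,
                 warnings = warns),
            class = "beam_mu_result")
}

#' Compare a calculated MU with the planning-system MU
#'
#' @param result A [compute_mu()] result.
#' @param mu_tps TPS-prescribed MU (> 0).
#' @return The result with `mu_tps` and
#'   `percent_diff = 100 (mu_calculated - mu_tps) / mu_tps` filled in
#'   (positive = the model predicts more MU than the TPS).
#' @export
compare_mu <- function(result, mu_tps) {
  stopifnot(inherits(result, "beam_mu_result"))
  if (!isTRUE(mu_tps > 0)) stop("mu_tps must be > 0")
  result$mu_tps <- mu_tps
  result$percent_diff <- 100 * (result$mu_calculated - mu_tps) / mu_tps
  result
}

#' Per-site summary of MU percent differences
#'
#' Sample mean and (n-1) standard deviation of the percent differences per
#' site group, plus a pooled "Total" row -- the layout of a per-site MU
#' verification report. For a single-beam group the SD is reported as 0 with
#' `sd_undefined = TRUE`.
#'
#' @param results List of [compare_mu()] results, or a data.frame with
#'   columns `site` and `percent_diff`.
#' @param sites Site label per result (recycled; ignored for data.frames).
#' @return Data frame with `site`, `n_beams`, `mean_pct`, `sd_pct`,
#'   `sd_undefined`; attribute `percent_diffs` holds the raw values for
#'   histogramming.
#' @export
summarize_mu <- function(results, sites = "all") {
  if (is.data.frame(results)) {
    df <- results
    stopifnot(all(c("site", "percent_diff") %in% names(df)))
  } else {
    pct <- vapply(results, function(r) {
      stopifnot(inherits(r, "beam_mu_result"))
      r$percent_diff
    }, numeric(1))
    df <- data.frame(site = rep_len(sites, length(pct)), percent_diff = pct)
  }
  df <- df[is.finite(df$percent_diff), , drop = FALSE]
  if (nrow(df) == 0L) stop("no results with a percent difference to summarize")
  one <- function(x, label) data.frame(
    site = label, n_beams = length(x), mean_pct = mean(x),
    sd_pct = if (length(x) > 1L) stats::sd(x) else 0,
    sd_undefined = length(x) < 2L)
  parts <- lapply(split(df$percent_diff, df$site), function(x) x)
  out <- do.call(rbind, c(unname(Map(one, parts, names(parts))),
                          list(one(df$percent_diff, "Total"))))
  rownames(out) <- NULL
  structure(out, percent_diffs = df$percent_diff)
}

#' Run the full secondary check on a synthetic or loaded case
#'
#' Measures volume, BEV area, distal water-equivalent depth and (for shifted
#' beams) air gap from the case geometry, builds the equivalent cuboid,
#' computes MU against the factor set, and compares with the case's
#' ground-truth/TPS MU when present.
#'
#' @param case A `mu_case` (from [generate_case()] or [read_case()]).
#' @param set A [factor_set()].
#' @param pixel_cm BEV raster resolution for the measurements (default: the
#'   mask voxel spacing).
#' @return A `beam_mu_result` with the measured cuboid attached.
#' @export
check_case <- function(case, set, pixel_cm = NULL) {
  stopifnot(inherits(case, "mu_case"))
  mask <- case$mask; beam <- case$beam
  if (is.null(pixel_cm)) pixel_cm <- min(mask$spacing)
  d <- beam_direction(beam$gantry_deg, beam$couch_deg)
  vol <- mask_volume(mask)
  area <- bev_projected_area(mask, d, pixel_cm)
  wed <- distal_surface_wed(mask, case$density, d, pixel_cm)
  gap <- if (beam$range_shifted) air_gap(case$density, beam, mask)
         else NA_real_
  cub <- cuboid_from_measurements(vol, area, wed$mean_cm, beam, gap)
  res <- compute_mu(case$prescribed_dose_cGy, cub, set)
  mu_ref <- case$mu_ground_truth %||% case$mu_tps
  if (!is.null(mu_ref) && is.finite(mu_ref)) res <- compare_mu(res, mu_ref)
  res$site <- case$site_label
  res
}
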