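# Interchange formats: the JSON case document (grid + run-length-encoded
# mask/density + beam + dose), and CSV/JSON result reports. All writers are
# deterministic; every writer/reader pair round-trips within serialization
# precision. Factor-table I/O lives in factors.R.

CASE_SCHEMA_VERSION <- 1L

rle_encode <- function(x) {
  r <- rle(as.vector(x))
  list(lengths = r$lengths, values = r$values)
}

rle_decode <- function(enc, shape) {
  array(inverse.rle(structure(list(lengths = as.integer(enc$lengths),
                                   values = enc$values), class = "rle")),
        dim = shape)
}

grid_header <- function(obj) list(origin = obj$origin, spacing = obj$spacing,
                                  shape = dim(obj[[3L]]))

#' Write a case to its JSON interchange document
#'
#' @param case A `mu_case` (see [generate_case()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_case <- function(case, path) {
  stopifnot(inherits(case, "mu_case"))
  doc <- list(
    schema_version = CASE_SCHEMA_VERSION,
    grid = grid_header(case$mask),
    mask = rle_encode(case$mask$occupancy),
    density = if (all(case$density$rsp == 1))
      list(type = "uniform_water", grid = grid_header(case$density))
    else list(type = "rle", grid = grid_header(case$density),
              rle = rle_encode(case$density$rsp)),
    beam = case$beam[c("gantry_deg", "couch_deg", "isocenter",
                       "range_shifted", "shifter_wet",
                       "shifter_face_distance")],
    prescribed_dose_cGy = case$prescribed_dose_cGy,
    mu_tps = case$mu_ground_truth %||% case$mu_tps,
    site_label = case$site_label)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Read a case from its JSON interchange document
#'
#' Validates the schema version and required fields; a density tagged
#' `uniform_water` is synthesized as an rsp = 1 grid.
#'
#' @param path Path to a case JSON file.
#' @return A `mu_case` object (`mu_tps` may be NA).
#' @export
read_case <- function(path) {
  if (!file.exists(path)) stop("case file not found: ", path)
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    stop("cannot parse case file ", path, ": ",
                         conditionMessage(e)))
  need <- c("schema_version", "grid", "mask", "density", "beam",
            "prescribed_dose_cGy")
  miss <- need[!need %in% names(doc)]
  if (length(miss))
    stop("case file ", path, " violates the schema; missing fields: ",
         paste(miss, collapse = ", "))
  if (doc$schema_version != CASE_SCHEMA_VERSION)
    stop("unsupported case schema version: ", doc$schema_version)
  mask <- voxel_mask(doc$grid$origin, doc$grid$spacing,
                     rle_decode(doc$mask, doc$grid$shape))
  den <- doc$density
  density <- if (identical(den$type, "uniform_water"))
    uniform_water_grid(den$grid$origin, den$grid$spacing, den$grid$shape)
  else density_grid(den$grid$origin, den$grid$spacing,
                    rle_decode(den$rle, den$grid$shape))
  b <- doc$beam
  beam <- beam_geometry(b$gantry_deg, b$couch_deg %||% 0,
                        b$isocenter %||% c(0, 0, 0),
                        range_shifted = isTRUE(b$range_shifted),
                        shifter_wet = b$shifter_wet %||% 4.1,
                        shifter_face_distance =
                          b$shifter_face_distance %||% NA_real_)
  structure(list(mask = mask, density = density, beam = beam,
                 prescribed_dose_cGy = doc$prescribed_dose_cGy,
                 mu_ground_truth = NULL,
                 mu_tps = if (is.null(doc$mu_tps)) NA_real_ else doc$mu_tps,
                 site_label = doc$site_label %||% "unspecified"),
            class = "mu_case")
}

results_frame <- function(results, beam_ids = NULL) {
  if (is.null(beam_ids))
    beam_ids <- names(results) %||% sprintf("beam_%03d", seq_along(results))
  if (is.null(names(beam_ids)) && any(beam_ids == ""))
    beam_ids[beam_ids == ""] <- sprintf("beam_%03d", which(beam_ids == ""))
  rows <- Map(function(r, id) {
    cub <- r$cuboid
    data.frame(beam_id = id, site = r$site %||% "unspecified",
               volume_cm3 = cub$volume_cm3, bev_area_cm2 = cub$bev_area_cm2,
               sobp_width_cm = cub$sobp_width_cm,
               range_cm = cub$effective_range_cm, gap_cm = cub$air_gap_cm,
               of = r$components[["of"]], df = r$components[["df"]],
               agf = r$components[["agf"]], mu_calc = r$mu_calculated,
               mu_tps = r$mu_tps, pct_diff = r$percent_diff,
               warnings = paste(r$warnings, collapse = "; "))
  }, results, beam_ids)
  df <- do.call(rbind, rows)
  if (is.null(df)) {
    df <- data.frame(beam_id = character(), site = character(),
                     volume_cm3 = numeric(), bev_area_cm2 = numeric(),
                     sobp_width_cm = numeric(), range_cm = numeric(),
                     gap_cm = numeric(), of = numeric(), df = numeric(),
                     agf = numeric(), mu_calc = numeric(),
                     mu_tps = numeric(), pct_diff = numeric(),
                     warnings = character())
  }
  df <- df[order(df$beam_id), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write a verification report
#'
#' One row per beam with the equivalent-cuboid quantities, factor
#' decomposition, calculated and TPS MU and their percent difference, ordered
#' by beam id with floats at fixed precision. The JSON form additionally
#' carries the per-site summary and the percent-difference histogram.
#'
#' @param results List of [compute_mu()]/[compare_mu()] results (optionally
#'   named by beam id).
#' @param path Output path.
#' @param format `"csv"` or `"json"`.
#' @return The report data frame, invisibly.
#' @export
write_report <- function(results, path, format = c("csv", "json")) {
  format <- match.arg(format)
  df <- results_frame(results)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) round(x, 6))
  if (format == "csv") {
    utils::write.csv(df, path, row.names = FALSE, na = "")
  } else {
    pct <- df$pct_diff[is.finite(df$pct_diff)]
    hist_part <- if (length(pct)) {
      h <- graphics::hist(pct, breaks = "Sturges", plot = FALSE)
      list(breaks = h$breaks, counts = h$counts)
    }
    summary_part <- if (length(pct))
      summarize_mu(data.frame(site = df$site[is.finite(df$pct_diff)],
                              percent_diff = pct))
    jsonlite::write_json(list(beams = df, summary = summary_part,
                              histogram = hist_part),
                         path, auto_unbox = TRUE, digits = NA, na = "null",
                         dataframe = "rows")
  }
  invisible(df)
}
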