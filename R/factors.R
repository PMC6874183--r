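# Empirical factor tables of the MU model: a 2-D output-factor table
# OF(BEV area, SOBP width) per delivery mode, and 1-D depth and air-gap
# correction tables normalized at their reference conditions (20 cm depth,
# 1 cm gap). Interpolation is bilinear (OF) and monotone piecewise-cubic
# Hermite (DF/AGF); queries outside a table clamp to the boundary and carry a
# machine-readable `clamped` flag rather than extrapolating, so a second-check
# tool fails safe.

#' 2-D output-factor table
#'
#' @param area_axis Strictly ascending BEV areas, cm^2.
#' @param width_axis Strictly ascending SOBP widths, cm.
#' @param values Matrix of output factors, cGy/MU, dimensions
#'   `length(area_axis)` x `length(width_axis)`; all > 0.
#' @return A `factor_table_2d` object.
#' @export
factor_table_2d <- function(area_axis, width_axis, values) {
  values <- as.matrix(values)
  if (any(diff(area_axis) <= 0) || any(diff(width_axis) <= 0))
    stop("factor table axes must be strictly ascending")
  if (!all(dim(values) == c(length(area_axis), length(width_axis))))
    stop("values matrix dimensions do not match the axes")
  if (any(!is.finite(values)) || any(values <= 0))
    stop("output factors must be finite and > 0")
  dimnames(values) <- NULL
  structure(list(area_axis = as.numeric(area_axis),
                 width_axis = as.numeric(width_axis), values = values),
            class = "factor_table_2d")
}

#' 1-D correction-factor table
#'
#' @param axis Strictly ascending abscissae (beam range in cm for the depth
#'   factor, air gap in cm for the air-gap factor).
#' @param values Dimensionless ratios, all > 0.
#' @return A `factor_table_1d` object.
#' @export
factor_table_1d <- function(axis, values) {
  if (any(diff(axis) <= 0)) stop("factor table axis must be strictly ascending")
  if (length(values) != length(axis)) stop("axis/values length mismatch")
  if (any(!is.finite(values)) || any(values <= 0))
    stop("factors must be finite and > 0")
  structure(list(axis = as.numeric(axis), values = as.numeric(values)),
            class = "factor_table_1d")
}

# Renormalize a 1-D table so that its interpolated value at the reference
# abscissa is exactly 1. Tables off by more than `tol` are data errors.
normalize_table_1d <- function(tab, ref, tol = 0.02, what = "table") {
  f <- interp_1d(tab, ref)
  if (abs(f$value - 1) > tol)
    stop(sprintf("%s value at reference %.3g is %.4f, more than %.0f%% from 1: refusing to renormalize a table inconsistent with its definition",
                 what, ref, f$value, 100 * tol))
  factor_table_1d(tab$axis, tab$values / f$value)
}

#' Assemble a validated factor set
#'
#' Bundles the open-field and range-shifted output-factor tables, the depth
#' and air-gap factor tables, the reference conditions they were tabulated
#' under, and the measured SOBP-center calibration (cGy/MU scale, default 1).
#' DF and AGF are renormalized to equal 1 at their reference abscissae; tables
#' whose reference value is off by more than 2% are rejected as data errors.
#'
#' @param of_open,of_shifted [factor_table_2d()] for open and range-shifted
#'   delivery (the same table may be passed for both).
#' @param df [factor_table_1d()] of depth factors vs water-equivalent beam
#'   range, cm.
#' @param agf [factor_table_1d()] of air-gap factors vs gap, cm; must cover
#'   the reference gap.
#' @param reference List with `depth_cm` (default 20), `gap_cm` (default 1)
#'   and `shifter_wet_cm` (default 4.1).
#' @param calibration Measured output scale, dimensionless multiplier on the
#'   tabulated cGy/MU (default 1.0 = model MU).
#' @return A `factor_set` object.
#' @export
factor_set <- function(of_open, of_shifted, df, agf,
                       reference = list(depth_cm = 20, gap_cm = 1,
                                        shifter_wet_cm = 4.1),
                       calibration = 1.0) {
  stopifnot(inherits(of_open, "factor_table_2d"),
            inherits(of_shifted, "factor_table_2d"),
            inherits(df, "factor_table_1d"), inherits(agf, "factor_table_1d"))
  for (f in c("depth_cm", "gap_cm", "shifter_wet_cm"))
    if (is.null(reference[[f]]) || !is.finite(reference[[f]]))
      stop("reference condition missing: ", f)
  if (!is.finite(calibration) || calibration <= 0)
    stop("calibration must be a positive scale")
  df <- normalize_table_1d(df, reference$depth_cm, what = "depth factor")
  agf <- normalize_table_1d(agf, reference$gap_cm, what = "air-gap factor")
  structure(list(of_open = of_open, of_shifted = of_shifted, df = df,
                 agf = agf, reference = reference, calibration = calibration),
            class = "factor_set")
}

# Monotone piecewise-cubic Hermite interpolation with clamp-to-boundary.
interp_1d <- function(tab, x, method = c("monotone_cubic", "linear")) {
  method <- match.arg(method)
  clamped <- x < tab$axis[1] | x > tab$axis[length(tab$axis)]
  xq <- pmin(pmax(x, tab$axis[1]), tab$axis[length(tab$axis)])
  v <- if (length(tab$axis) < 3L || method == "linear") {
    stats::approx(tab$axis, tab$values, xout = xq, rule = 2)$y
  } else {
    stats::splinefun(tab$axis, tab$values, method = "monoH.FC")(xq)
  }
  list(value = v, clamped = clamped)
}

# Bilinear interpolation with clamp-to-boundary.
interp_bilinear <- function(tab, area, width) {
  ax <- tab$area_axis; wx <- tab$width_axis
  clamped <- area < ax[1] | area > ax[length(ax)] |
    width < wx[1] | width > wx[length(wx)]
  a <- pmin(pmax(area, ax[1]), ax[length(ax)])
  w <- pmin(pmax(width, wx[1]), wx[length(wx)])
  i <- pmin(pmax(findInterval(a, ax), 1L), length(ax) - 1L)
  j <- pmin(pmax(findInterval(w, wx), 1L), length(wx) - 1L)
  fa <- (a - ax[i]) / (ax[i + 1L] - ax[i])
  fw <- (w - wx[j]) / (wx[j + 1L] - wx[j])
  v <- (1 - fa) * (1 - fw) * tab$values[cbind(i, j)] +
    fa * (1 - fw) * tab$values[cbind(i + 1L, j)] +
    (1 - fa) * fw * tab$values[cbind(i, j + 1L)] +
    fa * fw * tab$values[cbind(i + 1L, j + 1L)]
  list(value = v, clamped = clamped)
}

#' Output factor for a cuboid field
#'
#' Bilinear interpolation of the mode-appropriate output-factor table at the
#' given BEV area and SOBP width. Out-of-table queries clamp to the boundary;
#' the returned value carries attribute `clamped = TRUE` in that case.
#'
#' @param set A [factor_set()].
#' @param area_cm2 BEV projected area, cm^2 (> 0).
#' @param sobp_width_cm SOBP width, cm (> 0).
#' @param range_shifted Logical delivery mode.
#' @return Output factor, cGy/MU, with attribute `clamped`.
#' @export
output_factor <- function(set, area_cm2, sobp_width_cm, range_shifted = FALSE) {
  stopifnot(inherits(set, "factor_set"), area_cm2 > 0, sobp_width_cm > 0)
  tab <- if (range_shifted) set$of_shifted else set$of_open
  r <- interp_bilinear(tab, area_cm2, sobp_width_cm)
  structure(r$value, clamped = any(r$clamped))
}

#' Depth factor at a water-equivalent beam range
#'
#' Ratio of output at the given range to the reference depth (20 cm), by
#' monotone piecewise-cubic interpolation of the depth-factor table. Exactly
#' 1 at the reference after normalization.
#'
#' @param set A [factor_set()].
#' @param range_cm Water-equivalent beam range, cm (> 0).
#' @param method Interpolation method; linear is a fallback for sparse or
#'   non-smooth tables.
#' @return Dimensionless factor with attribute `clamped`.
#' @export
depth_factor <- function(set, range_cm,
                         method = c("monotone_cubic", "linear")) {
  stopifnot(inherits(set, "factor_set"), range_cm > 0)
  r <- interp_1d(set$df, range_cm, method)
  structure(r$value, clamped = any(r$clamped))
}

#' Air-gap factor
#'
#' For open (non-shifted) fields the factor is identically 1: the correction
#' is defined only for range-shifted delivery. For shifted fields, monotone
#' piecewise-cubic interpolation of the gap table, normalized to 1 at the
#' reference gap (1 cm).
#'
#' @param set A [factor_set()].
#' @param gap_cm Air gap, cm (>= 0).
#' @param range_shifted Logical delivery mode.
#' @param method As in [depth_factor()].
#' @return Dimensionless factor with attribute `clamped`.
#' @export
air_gap_factor <- function(set, gap_cm, range_shifted = FALSE,
                           method = c("monotone_cubic", "linear")) {
  stopifnot(inherits(set, "factor_set"), gap_cm >= 0)
  if (!range_shifted) return(structure(1.0, clamped = FALSE))
  r <- interp_1d(set$agf, gap_cm, method)
  structure(r$value, clamped = any(r$clamped))
}

#' Write a factor set to CSV tables plus a JSON sidecar
#'
#' Layout in `dir`: `of_open.csv` and `of_shifted.csv` with header
#' `sobp_width_cm,<area values...>` and one row per width; `df.csv` with
#' columns `range_cm,factor`; `agf.csv` with `gap_cm,factor`; and
#' `factors.json` holding the reference conditions and calibration.
#'
#' @param set A [factor_set()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_factor_set <- function(set, dir) {
  stopifnot(inherits(set, "factor_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_of <- function(tab, path) {
    m <- cbind(sobp_width_cm = tab$width_axis, t(tab$values))
    colnames(m) <- c("sobp_width_cm", format(tab$area_axis, trim = TRUE,
                                             digits = 15))
    utils::write.csv(m, path, row.names = FALSE, quote = FALSE)
  }
  write_of(set$of_open, file.path(dir, "of_open.csv"))
  write_of(set$of_shifted, file.path(dir, "of_shifted.csv"))
  utils::write.csv(data.frame(range_cm = set$df$axis, factor = set$df$values),
                   file.path(dir, "df.csv"), row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(gap_cm = set$agf$axis, factor = set$agf$values),
                   file.path(dir, "agf.csv"), row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(reference = set$reference,
                            calibration = set$calibration),
                       file.path(dir, "factors.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load and validate a factor set from a table directory
#'
#' Reads the CSV/JSON layout written by [write_factor_set()]. Rows may appear
#' in any order (they are sorted on load); axes must then be strictly
#' ascending, values positive, and the DF/AGF reference values within 2% of 1
#' (they are renormalized to exactly 1, per their definitions as ratios to the
#' reference conditions).
#'
#' @param dir Directory containing the tables.
#' @param calibration Optional override of the sidecar calibration.
#' @return A validated [factor_set()].
#' @export
load_factor_set <- function(dir, calibration = NULL) {
  need <- c("of_open.csv", "of_shifted.csv", "df.csv", "agf.csv",
            "factors.json")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing))
    stop("factor-set directory is missing: ", paste(missing, collapse = ", "))
  read_of <- function(path) {
    m <- utils::read.csv(path, check.names = FALSE)
    if (names(m)[1] != "sobp_width_cm")
      stop(path, ": first column must be sobp_width_cm")
    o <- order(m$sobp_width_cm)
    m <- m[o, , drop = FALSE]
    areas <- as.numeric(names(m)[-1])
    if (any(is.na(areas))) stop(path, ": area header values are not numeric")
    ao <- order(areas)
    factor_table_2d(areas[ao], m$sobp_width_cm,
                    t(as.matrix(m[, -1, drop = FALSE][, ao, drop = FALSE])))
  }
  read_1d <- function(path, xcol) {
    m <- utils::read.csv(path)
    if (!all(c(xcol, "factor") %in% names(m)))
      stop(path, ": expected columns ", xcol, ",factor")
    o <- order(m[[xcol]])
    factor_table_1d(m[[xcol]][o], m$factor[o])
  }
  side <- jsonlite::read_json(file.path(dir, "factors.json"),
                              simplifyVector = TRUE)
  factor_set(of_open = read_of(file.path(dir, "of_open.csv")),
             of_shifted = read_of(file.path(dir, "of_shifted.csv")),
             df = read_1d(file.path(dir, "df.csv"), "range_cm"),
             agf = read_1d(file.path(dir, "agf.csv"), "gap_cm"),
             reference = as.list(side$reference),
             calibration = if (is.null(calibration)) side$calibration
                           else calibration)
}
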