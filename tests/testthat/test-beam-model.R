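# Toy analytic beam model: pristine peaks, SOBP flattening, generated factor
# tables and synthetic cases.

test_that("bragg_curve satisfies the pristine-peak invariants", {
  cfg <- fx_config()
  for (r in c(4, 12, 20, 32)) {
    b <- bragg_curve(r, cfg)
    pk <- max(b$dose_per_mu)
    expect_lt(abs(b$depth_axis[which.max(b$dose_per_mu)] - r), 0.3)
    beyond <- b$depth_axis >= r + 1.5
    expect_lt(max(b$dose_per_mu[beyond]), 0.01 * pk)
    entrance <- b$dose_per_mu[which.min(abs(b$depth_axis - 0.5))]
    expect_gt(pk / entrance, 2)
    expect_true(all(b$dose_per_mu >= 0))
  }
  expect_error(bragg_curve(3.5, cfg), "band")
  expect_error(bragg_curve(33, cfg), "band")
  expect_identical(bragg_curve(17, cfg), bragg_curve(17, cfg))
})

test_that("bragg_curve integral grows monotonically with range", {
  cfg <- fx_config()
  ints <- vapply(seq(5, 31, by = 2), function(r) {
    b <- bragg_curve(r, cfg)
    sum(b$dose_per_mu) * diff(b$depth_axis[1:2])
  }, numeric(1))
  expect_true(all(diff(ints) > 0))
})

test_that("flatten_sobp reaches 2% plateau flatness and is deterministic", {
  cfg <- fx_config()
  for (w in c(2, 5, 10)) for (r in c(8, 20, 30)) {
    if (w >= r) next
    p <- flatten_sobp(r, w, cfg)
    expect_lte(p$flatness, 0.02)
    expect_true(all(p$weights >= 0))
    expect_equal(p$plateau, c(r - w, r))
  }
  expect_identical(flatten_sobp(20, 5, cfg), flatten_sobp(20, 5, cfg))
  expect_error(flatten_sobp(8, 9, cfg), "infeasible")
})

test_that("plateau dose per unit weight decreases with SOBP width", {
  cfg <- fx_config()
  tot <- vapply(c(2, 4, 6, 8), function(w)
    sum(flatten_sobp(20, w, cfg)$weights), numeric(1))
  expect_true(all(diff(1 / tot) < 0))
})

test_that("generated factor sets satisfy every factor invariant", {
  fs <- fx_factor_set()
  cfg <- fx_config()
  expect_equal(as.numeric(depth_factor(fs, 20)), 1, tolerance = 1e-6)
  expect_equal(as.numeric(air_gap_factor(fs, 1, TRUE)), 1, tolerance = 1e-6)
  expect_true(all(fs$of_open$values > 0))
  expect_true(all(fs$of_shifted$values > 0))
  # table domain: areas to 225 cm^2, widths to 10 cm, ranges 4-32, gaps 0-10
  expect_equal(max(fs$of_open$area_axis), 225)
  expect_equal(max(fs$of_open$width_axis), 10)
  expect_equal(range(fs$df$axis), c(4, 32))
  expect_equal(range(fs$agf$axis), c(0, 10))
  # AGF strictly decreasing beyond the reference gap (sigma grows with gap)
  past_ref <- fs$agf$values[fs$agf$axis >= 1]
  expect_true(all(diff(past_ref) < 0))
  # deterministic regeneration
  fs2 <- generate_factor_set(toy_model_config())
  expect_equal(fs2$of_open$values, fs$of_open$values, tolerance = 1e-12)
  expect_equal(fs2$df$values, fs$df$values, tolerance = 1e-12)
})

test_that("cuboid cases at tabulation conditions reproduce the factor model", {
  cfg <- fx_config()
  fs <- fx_factor_set()
  case <- generate_case(list(shape = "cuboid", size = c(5, 4, 5),
                             center_depth_cm = 18, site_label = "of_node"),
                        cfg, seed = 5)
  res <- check_case(case, fs)
  expect_lt(abs(res$percent_diff), 0.5)
  # parameter recovery: the case's implied output factor matches the table
  of_implied <- case$prescribed_dose_cGy / case$mu_ground_truth
  expect_lt(abs(of_implied / as.numeric(output_factor(fs, 25, 4)) - 1), 0.01)
})

test_that("generate_case is seed-deterministic and shape-sensitive", {
  cfg <- fx_config()
  spec <- list(shape = "blob", size = c(2.5, 2.5, 2.5), center_depth_cm = 9,
               site_label = "lung")
  c1 <- generate_case(spec, cfg, seed = 9)
  c2 <- generate_case(spec, cfg, seed = 9)
  expect_identical(c1$mask$occupancy, c2$mask$occupancy)
  expect_identical(c1$mu_ground_truth, c2$mu_ground_truth)
  c3 <- generate_case(spec, cfg, seed = 10)
  expect_false(identical(c1$mask$occupancy, c3$mask$occupancy))
  # ellipsoid ground truth differs from the cuboid model by a finite few
  # percent (the cuboid approximation is not exact for curved targets)
  ell <- generate_case(list(shape = "ellipsoid", size = c(3, 2.5, 3.5),
                            center_depth_cm = 15, site_label = "pelvis"),
                       cfg, seed = 5)
  res <- check_case(ell, fx_factor_set())
  expect_true(is.finite(res$percent_diff))
  expect_gt(abs(res$percent_diff), 0.5)
  expect_lt(abs(res$percent_diff), 10)
  # infeasible geometry is refused
  expect_error(generate_case(list(shape = "ellipsoid", size = c(3, 3, 3),
                                  center_depth_cm = 2.5), cfg, seed = 1),
               "infeasible")
})
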