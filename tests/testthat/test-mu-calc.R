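# Cuboid model arithmetic, MU factorization, comparison and summaries.

test_that("cuboid_from_measurements applies V/A and the range-shifter rule", {
  open_beam <- beam_geometry(0)
  shifted <- beam_geometry(0, range_shifted = TRUE, shifter_wet = 4.1,
                           shifter_face_distance = 20)
  cub <- cuboid_from_measurements(125, 25, 20, open_beam)
  expect_equal(cub$sobp_width_cm, 5)
  expect_equal(cub$effective_range_cm, 20)
  expect_equal(cub$sobp_width_cm * cub$bev_area_cm2, cub$volume_cm3,
               tolerance = 1e-12)
  expect_equal(cuboid_from_measurements(1500, 150, 25,
                                        open_beam)$sobp_width_cm, 10)
  # same geometry open vs shifted: ranges 10 vs 14.1
  expect_equal(cuboid_from_measurements(125, 25, 10, open_beam)$
                 effective_range_cm, 10)
  expect_equal(cuboid_from_measurements(125, 25, 10, shifted,
                                        gap_cm = 2)$effective_range_cm, 14.1)
  expect_error(cuboid_from_measurements(-1, 25, 10, open_beam), "positive")
  # V/A width exceeding the range is pathological, not truncated
  expect_error(cuboid_from_measurements(1000, 50, 8, open_beam),
               "pathological")
  expect_error(cuboid_from_measurements(125, 25, 10, shifted), "gap_cm")
})

test_that("compute_mu is the factor product with identity and scaling laws", {
  fs <- unit_factor_set()
  beam <- beam_geometry(0)
  cub <- cuboid_from_measurements(125, 25, 20, beam)
  res <- compute_mu(200, cub, fs)
  expect_equal(res$mu_calculated, 200)
  expect_equal(unname(res$components), c(1, 1, 1, 1))
  # degree 1 in dose
  expect_equal(compute_mu(400, cub, fs)$mu_calculated, 400)
  # degree -1 in calibration
  fs2 <- unit_factor_set(calibration = 2)
  expect_equal(compute_mu(200, cub, fs2)$mu_calculated, 100)
  expect_equal(res$mu_calculated,
               200 / prod(res$components), tolerance = 1e-12)
  expect_error(compute_mu(200, cub, fs, multifield = TRUE), "SFUD")
  expect_error(compute_mu(-5, cub, fs), "dose")
})

test_that("compute_mu propagates clamp warnings from the tables", {
  fs <- fx_factor_set()
  beam <- beam_geometry(0)
  inside <- compute_mu(200, cuboid_from_measurements(125, 25, 20, beam), fs)
  expect_length(inside$warnings, 0)
  outside <- compute_mu(200, cuboid_from_measurements(2560, 256, 28, beam),
                        fs)
  expect_true(any(grepl("output factor clamped", outside$warnings)))
})

test_that("MU is continuous in area/width/range across table nodes", {
  fs <- fx_factor_set()
  beam <- beam_geometry(0)
  eps <- 1e-7
  for (probe in list(c(a = 25, w = 5, r = 20), c(a = 49, w = 3, r = 18))) {
    mu <- vapply(c(-eps, 0, eps), function(h) {
      cub <- cuboid_from_measurements((probe["a"] + h) * probe["w"],
                                      probe["a"] + h, probe["r"] + h, beam)
      compute_mu(100, cub, fs)$mu_calculated
    }, numeric(1))
    expect_lt(max(abs(diff(mu))) / mu[2], 1e-5)
  }
})

test_that("compare_mu computes the signed percent difference", {
  fs <- unit_factor_set()
  res <- compute_mu(100, cuboid_from_measurements(125, 25, 20,
                                                  beam_geometry(0)), fs)
  expect_equal(compare_mu(res, 100)$percent_diff, 0)
  expect_equal(compare_mu(res, 100)$mu_tps, 100)
  res99 <- compute_mu(99, cuboid_from_measurements(125, 25, 20,
                                                   beam_geometry(0)), fs)
  expect_equal(compare_mu(res99, 100)$percent_diff, -1)
  expect_error(compare_mu(res, -1), "mu_tps")
})

test_that("summarize_mu reproduces hand-computed statistics", {
  one <- summarize_mu(data.frame(site = "brain", percent_diff = 0))
  expect_equal(one$mean_pct, c(0, 0))
  expect_equal(one$sd_pct, c(0, 0))
  expect_true(all(one$sd_undefined))
  two <- summarize_mu(data.frame(site = c("a", "a"),
                                 percent_diff = c(1, -1)))
  tot <- two[two$site == "Total", ]
  expect_equal(tot$mean_pct, 0)
  expect_equal(tot$sd_pct, sqrt(2))
  expect_false(tot$sd_undefined)
  mixed <- summarize_mu(data.frame(site = c("a", "a", "b"),
                                   percent_diff = c(2, 4, -3)))
  expect_equal(mixed$n_beams[mixed$site == "Total"], 3)
  expect_equal(mixed$mean_pct[mixed$site == "a"], 3)
  expect_equal(mixed$mean_pct[mixed$site == "Total"], 1)
  expect_error(summarize_mu(data.frame(site = character(),
                                       percent_diff = numeric())),
               "no results")
})
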