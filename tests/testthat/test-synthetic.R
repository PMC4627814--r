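test_that("contour generation is deterministic under a fixed seed", {
  sp <- synthetic_spec(seed = 21)
  c1 <- generate_contour(sp, 60)
  c2 <- generate_contour(sp, 60)
  expect_identical(c1$x, c2$x)
  expect_identical(c1$y, c2$y)
  sp2 <- synthetic_spec(seed = 22)
  c3 <- generate_contour(sp2, 60)
  expect_false(identical(c1$x, c3$x))
})

test_that("injected point noise has the requested amplitude", {
  sp <- synthetic_spec(noise_sd = 1, axis_offset = 0, skew_amp = 0,
                       spacing = 0.35, seed = 4)   # dense: ~1000 points
  sol <- solve_shape(sp$params, L = 60)
  ct <- generate_contour(sp, 60, solution = sol)
  expect_gt(nrow(ct), 400)  # ~1000 coordinates for the SD check
  # residual displacement against the clean mirrored profile
  clean <- generate_contour(
    synthetic_spec(noise_sd = 0, axis_offset = 0, skew_amp = 0,
                   spacing = 0.35, seed = 4), 60, solution = sol)
  dx <- ct$x - clean$x; dy <- ct$y - clean$y
  expect_equal(sd(c(dx, dy)), 1, tolerance = 0.1)
})

test_that("generated shapes match the tomogram geometry scale", {
  # at the fitted parameter scale the tip radius is close to the measured
  # ~12 nm
  sp <- synthetic_spec(seed = 2)
  sol <- solve_shape(sp$params, L = 60)
  expect_equal(sol$observables$tip_radius, 12, tolerance = 0.3)
})

test_that("the benchmark suite is rectifiable and carries ground truth", {
  dir <- tempfile()
  suite <- make_benchmark_suite(synthetic_spec(seed = 11), dir = dir)
  expect_gte(length(suite$contours), 6)
  expect_true(file.exists(file.path(dir, "truth.json")))
  for (nm in names(suite$contours)) {
    rp <- rectify_contour(suite$contours[[nm]])
    expect_s3_class(rp, "rectified_profile")
    expect_gt(attr(rp, "L"), 5)
  }
  # the near-closure member has a tight neck
  tr <- suite$truth$contour_nearclosure
  expect_lt(tr$neck_radius, 0.2 * tr$R_Pi)
  # the necked member has a genuine neck too
  expect_true(is.finite(suite$truth$contour_necked$neck_radius))
  # round-trip from disk
  ct <- read_contour_csv(file.path(dir, "contour_L060.csv"))
  expect_s3_class(ct, "contour2d")
  expect_equal(nrow(ct), nrow(suite$contours$contour_L060))
})

test_that("suite recovery: fits find the generating scale within 10 percent", {
  dir <- tempfile()
  suite <- make_benchmark_suite(synthetic_spec(seed = 13), dir = dir)
  ca <- fit_cache()
  rp <- rectify_contour(suite$contours$contour_L060)
  fit <- fit_profile(rp, grid_R_Pi = seq(12, 30, length.out = 5),
                     grid_sigma = 0, grid_c0 = c(0.2, 0.4, 0.6), cache = ca)
  expect_equal(fit$R_Pi, 20, tolerance = 0.1)
})
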