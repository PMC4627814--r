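test_that("rectification inverts a clean mirrored contour exactly", {
  # fine sampling so that chord error at the tip does not mask the check
  sp <- synthetic_spec(noise_sd = 0, axis_offset = 0, skew_amp = 0, seed = 1,
                       spacing = 1.5)
  ct <- generate_contour(sp, 40)
  rp <- rectify_contour(ct, n_out = 120)
  expect_lt(attr(rp, "asymmetry"), 1e-9)
  expect_equal(attr(rp, "L"), 40, tolerance = 1e-6)
  # the rectified radii match the generating model profile
  sol <- solve_shape(sp$params, L = 40)
  d <- endomech:::.pts_to_polyline(cbind(rp$r, rp$z)[rp$z > 1, ],
                                   cbind(sol$profile$r, sol$profile$z))
  expect_lt(max(d), 0.08)
})

test_that("rectification recovers an offset axis and scores asymmetry with noise", {
  sp <- synthetic_spec(noise_sd = 0, axis_offset = 3, skew_amp = 0, seed = 2)
  ct <- generate_contour(sp, 40)
  rp <- rectify_contour(ct)
  expect_equal(attr(rp, "axis_x"), 3, tolerance = 0.5)
  # asymmetry score grows with injected point noise (Monte-Carlo)
  scores <- vapply(c(0.5, 1, 2), function(ns) {
    sps <- synthetic_spec(noise_sd = ns, axis_offset = 0, skew_amp = 0,
                          seed = 5)
    mean(vapply(1:4, function(k) {
      sps$seed <- 5L + k
      attr(rectify_contour(generate_contour(sps, 40)), "asymmetry")
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(scores) > 0))
})

test_that("rectification rejects degenerate contours", {
  expect_error(contour2d(1:5, 1:5), "at least 10")
  # apex on the boundary
  bad <- contour2d(seq(0, 10, length.out = 20), seq(0, 20, length.out = 20))
  expect_error(rectify_contour(bad), "apex")
})

test_that("noiseless forward-model profiles are recovered nearly exactly", {
  sp <- synthetic_spec(noise_sd = 0, axis_offset = 0, skew_amp = 0, seed = 3,
                       spacing = 1.5)
  rp <- rectify_contour(generate_contour(sp, 60))
  fit <- fit_profile(rp, grid_R_Pi = c(10, 15, 20, 25, 30), grid_sigma = 0,
                     grid_c0 = c(0, 0.2, 0.4, 0.6))
  expect_equal(fit$R_Pi, 20, tolerance = 0.01)
  expect_equal(fit$c0_nd, 0.4, tolerance = 0.02)
  expect_lt(fit$residual, 0.1)
  expect_equal(unname(coef(fit)["R_Pi"]), fit$R_Pi)
  expect_output(print(fit), "R_Pi")
})

test_that("the fitted force is unique given the parameters and height", {
  sp <- synthetic_spec(noise_sd = 0, axis_offset = 0, skew_amp = 0, seed = 3)
  rp <- rectify_contour(generate_contour(sp, 60))
  fit <- fit_profile(rp, grid_R_Pi = 20, grid_sigma = 0, grid_c0 = 0.4,
                     refine = FALSE)
  truth <- attr(generate_contour(sp, 60), "truth")
  expect_equal(fit$f_nd * derived_scales(sp$params)$f_Pi, truth$f_a,
               tolerance = 0.02)
})

test_that("degeneracy: a range of tensions fits tension-free synthetic data", {
  sp <- synthetic_spec(noise_sd = 1, seed = 9)
  rp <- rectify_contour(generate_contour(sp, 60))
  fit <- fit_profile(rp, grid_R_Pi = c(18, 20, 22),
                     grid_sigma = c(0, 0.04, 0.08), grid_c0 = c(0.35, 0.4, 0.45),
                     refine = FALSE, degeneracy_tol = 1.1)
  expect_gt(nrow(fit$degenerate_set), 1)
  expect_true(any(fit$degenerate_set$sigma_nd > 0))
  expect_true(all(fit$degenerate_set$residual >= fit$residual - 1e-12))
})

test_that("best-fit residual does not improve with more injected noise", {
  res <- vapply(c(0, 1, 2.5), function(ns) {
    sp <- synthetic_spec(noise_sd = ns, axis_offset = 0, skew_amp = 0,
                         seed = 17)
    rp <- rectify_contour(generate_contour(sp, 60))
    fit_profile(rp, grid_R_Pi = c(16, 20, 24), grid_sigma = 0,
                grid_c0 = c(0.3, 0.4, 0.5), refine = FALSE)$residual
  }, numeric(1))
  expect_true(all(diff(res) > 0))
})

test_that("fit_report converts to physical parameters with correct scaling", {
  fit <- structure(list(R_Pi = 16, sigma_nd = 0, c0_nd = 0.4,
                        f_nd = 0.5, residual = 0.5, bounds = NULL,
                        degenerate_set = data.frame()),
                   class = "invagination_fit")
  rep1 <- fit_report(fit, Pi_assumed = 1)
  expect_equal(rep1$kappa_pN_nm, 2 * 16^3, tolerance = 1e-12)
  expect_equal(rep1$kappa_kBT, 8192 / 4.1, tolerance = 1e-12)
  fit$R_Pi <- 20
  expect_equal(fit_report(fit, 1)$coat_radius_nm, 100, tolerance = 1e-12)
  # kappa scales linearly in the assumed pressure
  expect_equal(fit_report(fit, 0.2)$kappa_pN_nm,
               0.2 * fit_report(fit, 1)$kappa_pN_nm, tolerance = 1e-12)
})
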