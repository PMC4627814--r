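test_that("long invaginations approach the analytic tube asymptote", {
  p <- base_params()
  s6 <- solve_shape(p, L = 6 * RPI)
  tl <- tube_limit(p)
  # approach to the plateau is still ~3% at L = 6 R_Pi ...
  expect_equal(s6$f_a / FPI, tl$force_nd, tolerance = 0.05)
  mid <- s6$profile$r[s6$profile$z > 0.3 * s6$L & s6$profile$z < 0.7 * s6$L]
  expect_equal(mean(mid) / RPI, tl$radius_nd, tolerance = 0.08)
  # ... and well within 3% by L = 8 R_Pi
  s8 <- solve_shape(p, L = 8 * RPI, guess = s6$nondim)
  expect_equal(s8$f_a / FPI, tl$force_nd, tolerance = 0.03)
})

test_that("solution is self-consistent: stored energies, quadrature, residual", {
  p <- base_params(c0_nd = 0.4)
  s <- solve_shape(p, L = 2 * RPI)
  expect_true(s$converged)
  expect_lt(s$residual, 1e-8)
  expect_lt(abs(s$nondim$H_end), 1e-5)   # free-arclength first integral
  e <- evaluate_energy(s$profile, p, f_a = s$f_a)
  for (nm in c("E_bend", "E_pressure", "E_deform"))
    expect_equal(e[[nm]], s$energies[[nm]], tolerance = 5e-3)
  ob <- geometric_observables(s$profile)
  expect_equal(ob$V, s$observables$V, tolerance = 5e-3)
  expect_equal(ob$S, s$observables$S, tolerance = 5e-3)
  # boundary values
  n <- nrow(s$profile)
  expect_lt(abs(s$profile$psi[n]), 1e-6)
  expect_lt(s$profile$z[n], 1e-6)
  expect_equal(s$profile$z[1], s$L, tolerance = 1e-9)
})

test_that("apical force is conjugate to height (f = dE/dL)", {
  p <- base_params(c0_nd = 0.4)
  s0 <- solve_shape(p, L = 2 * RPI)
  dL <- 0.05 * RPI
  sp <- solve_shape(p, L = 2 * RPI + dL, guess = s0$nondim)
  sm <- solve_shape(p, L = 2 * RPI - dL, guess = s0$nondim)
  dEdL <- (sp$energies$E_deform - sm$energies$E_deform) / (2 * dL)
  expect_equal(dEdL, s0$f_a, tolerance = 0.03)
})

test_that("force mode and height mode are mutually consistent", {
  p <- base_params()
  sL <- solve_shape(p, L = 3 * RPI)
  sf <- solve_shape(p, f_a = sL$f_a, guess = sL$nondim)
  expect_equal(sf$L, sL$L, tolerance = 1e-5)
})

test_that("solutions are scale invariant after nondimensionalization", {
  for (cc in c(0.2, 5)) {
    p1 <- base_params(c0_nd = 0.4)
    p2 <- model_params(kappa = 160 * cc, sigma = 0, Pi = cc,
                       C0 = 0.4 / RPI)   # same R_Pi, scaled kappa & Pi
    s1 <- solve_shape(p1, L = 2 * RPI)
    s2 <- solve_shape(p2, L = 2 * RPI, guess = s1$nondim)
    expect_equal(s2$f_a / derived_scales(p2)$f_Pi,
                 s1$f_a / FPI, tolerance = 1e-6)
    expect_equal(s2$nondim$Sigma, s1$nondim$Sigma, tolerance = 1e-6)
  }
})

test_that("apical force increases with membrane tension at fixed height", {
  fs <- vapply(c(0, 0.05, 0.15), function(sg) {
    p <- base_params(c0_nd = 0.2, sig_nd = sg)
    solve_shape(p, L = 2 * RPI)$f_a / FPI
  }, numeric(1))
  expect_true(all(diff(fs) > 0))
})

test_that("a vanishing BAR rigidity reproduces the isotropic solver", {
  p0 <- base_params(c0_nd = 0.3)
  pG <- model_params(kappa = 160, Pi = 1, C0 = 0.3 / RPI, Gamma = 0,
                     R0 = RPI)
  s0 <- solve_shape(p0, L = 2 * RPI)
  sG <- solve_shape(pG, L = 2 * RPI)
  expect_equal(sG$f_a, s0$f_a, tolerance = 1e-9)
})

test_that("no-equilibrium heights raise a catchable condition", {
  p <- base_params(c0_nd = 1)
  # the gap regime: pick a height between the fold of the short branch and
  # the foot of the tall branch
  expect_error(solve_shape(p, L = 2 * RPI),
               class = "endomech_no_equilibrium")
})

test_that("direct minimization refines toward a stable energy with n_nodes", {
  p <- base_params(c0_nd = 0.2)
  Es <- vapply(c(100, 200, 300), function(n)
    direct_minimization(p, L = 1.5 * RPI, n_nodes = n)$E_deform, numeric(1))
  # discretization error shrinks under refinement
  expect_lt(abs(Es[3] - Es[2]), abs(Es[2] - Es[1]) + 1e-9)
  expect_equal(Es[2], Es[3], tolerance = 1e-3)
})

test_that("heterogeneous rigidity: uniform ratio reproduces the homogeneous path", {
  p <- base_params()
  rg <- rigidity_profile(160, 160, A_tip = 300, w = 3)
  s1 <- solve_heterogeneous(p, rg, L = 3 * RPI)
  s0 <- solve_shape(p, L = 3 * RPI)
  expect_identical(s1$f_a, s0$f_a)
})

test_that("a softer base lowers the force and a too-soft base destabilizes", {
  p <- base_params()
  A_tip <- 2 * pi * RPI^2 * 1.5
  rg_soft <- rigidity_profile(160, 80, A_tip = A_tip, w = 2)
  s_soft <- solve_heterogeneous(p, rg_soft, L = 3 * RPI)
  s_hom <- solve_shape(p, L = 3 * RPI)
  expect_lt(s_soft$f_a, s_hom$f_a)
  expect_true(is.finite(s_soft$f_a))
  # rigidity instability: very soft base has no equilibrium over the range
  rg_bad <- rigidity_profile(160, 160 * 0.02, A_tip = A_tip, w = 2)
  expect_error(solve_heterogeneous(p, rg_bad, L = 4 * RPI),
               class = "endomech_no_equilibrium")
})

test_that("solution printing and plotting run quietly", {
  s <- solve_shape(base_params(), L = 2 * RPI)
  expect_output(print(s), "Equilibrium invagination")
  expect_output(summary(s), "Energy breakdown")
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  expect_silent(plot(s))
})

test_that("the rigidity-instability threshold shifts with the stiff-cap area", {
  # at the same base softness (10% of the tip rigidity), a small stiff cap
  # is unstable while a large one still supports the invagination
  p <- base_params()
  small <- rigidity_profile(160, 16, A_tip = 2 * pi * RPI^2 * 0.5, w = 2)
  large <- rigidity_profile(160, 16, A_tip = 2 * pi * RPI^2 * 3, w = 2)
  expect_error(solve_heterogeneous(p, small, L = 3 * RPI),
               class = "endomech_no_equilibrium")
  s <- solve_heterogeneous(p, large, L = 3 * RPI)
  expect_true(s$converged)
  expect_gt(s$f_a, 0)
})
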