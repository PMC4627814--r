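test_that("derived scales follow the closed forms and the force-scale identity", {
  p <- model_params(kappa = 160, sigma = 1, Pi = 1)
  sc <- derived_scales(p)
  expect_equal(sc$R_Pi, 80^(1 / 3), tolerance = 1e-12)
  expect_equal(sc$lambda, sqrt(80), tolerance = 1e-12)
  expect_equal(sc$f_Pi, 4 * pi * sc$R_Pi^2, tolerance = 1e-12)
  # identity f_Pi = 2 pi kappa / R_Pi = 4 pi Pi R_Pi^2 for random parameters
  set.seed(42)
  for (k in 1:20) {
    kap <- runif(1, 20, 5000); Pi <- runif(1, 0.05, 3)
    sci <- derived_scales(model_params(kappa = kap, Pi = Pi))
    expect_equal(2 * pi * kap / sci$R_Pi, 4 * pi * Pi * sci$R_Pi^2,
                 tolerance = 1e-12)
  }
  # sigma = 0 gives an infinite tension length
  expect_identical(derived_scales(model_params(kappa = 160, Pi = 1))$lambda,
                   Inf)
})

test_that("parameter validation rejects unphysical inputs", {
  expect_error(model_params(kappa = -1, Pi = 1), "kappa")
  expect_error(model_params(kappa = 160, Pi = 0), "Pi")
  expect_error(model_params(kappa = 160, Pi = 1, sigma = -0.1), "sigma")
  expect_error(model_params(kappa = 160, Pi = 1, Gamma = 100), "R0")
})

test_that("energy evaluator matches closed forms on analytic profiles", {
  p0 <- model_params(kappa = 160, Pi = 1)
  # full sphere: bending energy 8 pi kappa independent of radius
  for (R in c(5, 20)) {
    e <- evaluate_energy(sphere_profile(R),
                         model_params(kappa = 160, Pi = 1e-12), 0)
    expect_equal(e$E_bend, 8 * pi * 160, tolerance = 2e-3)
  }
  # sphere with matching spontaneous curvature: zero bending energy
  R <- 10
  eC <- evaluate_energy(sphere_profile(R),
                        model_params(kappa = 160, Pi = 1e-12, C0 = 2 / R), 0)
  expect_lt(eC$E_bend / (8 * pi * 160), 1e-4)
  # spherical cap: area and volume closed forms
  h <- 6; R <- 10
  ob <- geometric_observables(cap_profile(R, h))
  expect_equal(ob$V, pi * h^2 * (R - h / 3), tolerance = 1e-4)
  expect_equal(ob$S, 2 * pi * R * h, tolerance = 1e-4)
  expect_equal(ob$tip_radius, R, tolerance = 1e-3)
  # cylinder at the natural radius: bending + pressure per unit length
  len <- 30
  ecyl <- evaluate_energy(cylinder_profile(RPI, len), p0, 0)
  expect_equal(ecyl$E_bend + ecyl$E_pressure, 1.5 * pi * 160 * len / RPI,
               tolerance = 1e-4)
  # BAR term vanishes on a cylinder at the preferred radius
  pb <- model_params(kappa = 160, Pi = 1, Gamma = 160, R0 = RPI)
  eb <- evaluate_energy(cylinder_profile(RPI, len), pb, 0)
  expect_lt(abs(eb$E_bar), 1e-8)
  # and is positive away from it
  eb2 <- evaluate_energy(cylinder_profile(2 * RPI, len), pb, 0)
  expect_gt(eb2$E_bar, 1)
})

test_that("energy evaluator refines under grid refinement and guards inputs", {
  p0 <- model_params(kappa = 160, Pi = 1)
  exact <- 8 * pi * 160
  errs <- vapply(c(200, 400, 800), function(n) {
    abs(evaluate_energy(sphere_profile(10, n = n),
                        model_params(kappa = 160, Pi = 1e-12), 0)$E_bend -
          exact)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_error(evaluate_energy(cap_profile(10, 5, n = 20), p0), "coarse")
  bad <- cap_profile(10, 5)
  bad$r[5] <- -1
  expect_error(evaluate_energy(bad, p0), "negative|invalid")
})

test_that("energy breakdown sums exactly and work term enters F_total", {
  p <- model_params(kappa = 160, Pi = 1, C0 = 0.05)
  pr <- cap_profile(10, 6)
  e <- evaluate_energy(pr, p, f_a = 100)
  expect_identical(e$F_total,
                   e$E_bend + e$E_tension + e$E_pressure + e$E_bar +
                     e$E_bar_ref + e$work)
  expect_equal(e$E_deform, e$F_total - e$work, tolerance = 1e-12)
  expect_equal(e$work, -100 * pr$z[1], tolerance = 1e-12)
  expect_gte(e$E_bend, 0); expect_gte(e$E_pressure, 0)
})

test_that("initiation force reduces to 4 pi kappa C0 without tension", {
  p <- base_params(c0_nd = 0.4)
  expect_equal(initiation_force(p), 4 * pi * 160 * p$C0, tolerance = 1e-12)
  expect_equal(initiation_force(p) / FPI, 0.8, tolerance = 1e-12)
  expect_identical(initiation_force(base_params()), 0)
})

test_that("initiation force with tension matches the numerical L->0 limit", {
  # candidate closed form f0 = 4 pi kappa sqrt(C0^2 + 2 sigma / kappa),
  # cross-checked against extrapolated boundary-value solves
  p <- base_params(c0_nd = 0.4, sig_nd = 0.05)
  sc <- derived_scales(p)
  nd <- endomech:::nondim_params(p)
  Ls <- c(0.1, 0.05, 0.03, 0.02, 0.012)
  g <- NULL
  fs <- vapply(Ls, function(L) {
    s <- endomech:::.solve_nd(nd, L = L, guess = g)
    g <<- s
    s$ftil
  }, numeric(1))
  f0_num <- unname(coef(lm(fs ~ sqrt(Ls) + Ls))[1]) * sc$f_Pi
  expect_equal(f0_num, initiation_force(p), tolerance = 0.02)
})

test_that("tube limit reproduces closed forms and tension monotonicity", {
  tl0 <- tube_limit(base_params())
  expect_equal(tl0$radius_nd, 1, tolerance = 1e-6)
  expect_equal(tl0$force_nd, 0.75, tolerance = 1e-6)
  # independent 1-D minimization oracle at c0_nd = 0.4
  elen <- function(rho, c0, sig) 0.5 * rho * (1 / rho - c0)^2 +
    sig * rho + 0.25 * rho^2
  op <- optimize(elen, c(0.01, 10), c0 = 0.4, sig = 0, tol = 1e-12)
  tl <- tube_limit(base_params(c0_nd = 0.4))
  expect_equal(tl$radius_nd, op$minimum, tolerance = 1e-8)
  expect_equal(tl$force_nd, op$objective, tolerance = 1e-10)
  expect_equal(tl$radius_nd, 0.948, tolerance = 1e-2)
  expect_equal(tl$force_nd, 0.43, tolerance = 2e-2)
  # force grows and radius shrinks with tension
  sig <- c(0, 0.05, 0.15, 0.3)
  tls <- lapply(sig, function(s) tube_limit(base_params(sig_nd = s)))
  expect_true(all(diff(vapply(tls, `[[`, 1, "force_nd")) > 0))
  expect_true(all(diff(vapply(tls, `[[`, 1, "radius_nd")) < 0))
})

test_that("quasi-static timescale and coat-adhesion force are simple laws", {
  t1 <- quasistatic_timescale(L = 100, eta_m = 1e-8, f = 300)
  expect_equal(t1, 100 * 1e-8 / 300 * 1e3, tolerance = 1e-12)
  expect_lt(t1, 1e-4)   # orders of magnitude below the seconds-long event
  expect_equal(quasistatic_timescale(0, 1e-8, 300), 0)
  expect_equal(quasistatic_timescale(100, 1e-8, 600), t1 / 2,
               tolerance = 1e-12)
  expect_error(quasistatic_timescale(100, 1e-8, 0))
  expect_equal(coat_adhesion_force(1, 10), pi * 10, tolerance = 1e-12)
  expect_equal(coat_adhesion_force(0.1, 10), pi, tolerance = 1e-12)
  expect_identical(coat_adhesion_force(0, 10), 0)
})
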