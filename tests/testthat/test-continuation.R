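test_that("without spontaneous curvature the force is minimal at L = 0 and plateaus", {
  cv <- trace_branch(base_params())
  b <- cv$branches[order(cv$branches$L_nd), ]
  expect_identical(unique(b$branch_id), 1L)
  expect_null(cv$fold_points)
  expect_true(all(b$stable))
  # the force minimum sits at the flat end (no initiation barrier) ...
  expect_identical(which.min(b$f_nd), 1L)
  # ... and the curve settles onto the tube force at long heights (after a
  # finite tether-formation overshoot)
  expect_equal(b$f_nd[which.max(b$L_nd)],
               tube_limit(base_params())$force_nd, tolerance = 0.05)
})

test_that("the fitted-parameter curve peaks early and dips near 3 R_Pi", {
  p <- base_params(c0_nd = 0.4)
  cv <- trace_branch(p)
  b <- cv$branches[order(cv$branches$L_nd), ]
  imax <- which.max(b$f_nd)
  Lmax <- b$L_nd[imax]
  expect_gt(Lmax, 0.5); expect_lt(Lmax, 2)  # snap-through: early maximum
  after <- b[b$L_nd > Lmax, ]
  imin <- which.min(after$f_nd)
  expect_equal(after$L_nd[imin], 3, tolerance = 0.15)
  # the early maximum exceeds both the initiation force and the plateau
  f0 <- initiation_force(p) / FPI
  expect_gt(b$f_nd[imax], f0)
  expect_gt(b$f_nd[imax], tube_limit(p)$force_nd)
  # initiation-to-maximum ratio close to the analytic f0 over the peak
  expect_equal(f0 / b$f_nd[imax], 0.6, tolerance = 0.08)
})

test_that("force equals dE/dL along a traced branch", {
  cv <- trace_branch(base_params(c0_nd = 0.4), L_range = c(0, 4 * RPI))
  b <- cv$branches[order(cv$branches$L_nd), ]
  b <- b[b$L_nd > 0.3 & b$L_nd < 3.8, ]
  n <- nrow(b)
  dEdL <- (b$E_nd[3:n] - b$E_nd[1:(n - 2)]) / (b$L_nd[3:n] - b$L_nd[1:(n - 2)])
  fmid <- b$f_nd[2:(n - 1)]
  keep <- abs(fmid) > 0.15          # relative comparison away from the dip
  expect_lt(stats::median(abs(dEdL[keep] / fmid[keep] - 1)), 0.03)
})

test_that("hysteresis shows two branches with a force loop at equal height", {
  cv <- trace_branch(base_params(c0_nd = 0.45))
  b <- cv$branches
  expect_setequal(unique(b$branch_id), c(1L, 2L))
  b1 <- b[b$branch_id == 1 & b$stable, ]
  b2 <- b[b$branch_id == 2 & b$stable, ]
  Lov <- c(max(min(b2$L_nd), min(b1$L_nd)), min(max(b1$L_nd), max(b2$L_nd)))
  expect_gt(diff(Lov), 0.05)        # overlapping height support
  Ls <- mean(Lov)
  f1 <- approx(b1$L_nd, b1$f_nd, Ls, ties = mean)$y
  f2 <- approx(b2$L_nd, b2$f_nd, Ls, ties = mean)$y
  expect_gt(abs(f1 - f2), 0.05)     # distinct forces: a hysteresis loop
  expect_false(is.null(cv$fold_points))
})

test_that("neck radius varies continuously along a branch", {
  cv <- trace_branch(base_params(c0_nd = 0.45))
  b2 <- cv$branches[cv$branches$branch_id == 2, ]
  nk <- b2$neck_nd[!is.na(b2$neck_nd)]
  expect_gt(length(nk), 5)
  expect_lt(max(abs(diff(nk))), 0.3)   # no jumps along the branch
})

test_that("curve objects print and export to CSV", {
  cv <- trace_branch(base_params(), L_range = c(0, 3 * RPI))
  expect_output(print(cv), "branch")
  f <- tempfile(fileext = ".csv")
  write_curve_csv(cv, f)
  df <- read.csv(f)
  expect_named(df, c("branch_id", "L_nm", "fa_pN", "E_pNnm", "neck_nm",
                     "stable"))
  expect_gt(nrow(df), 10)
})
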