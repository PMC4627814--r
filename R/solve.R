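# Core boundary-value solver.  All internal work is nondimensional: lengths in
# R_Pi, forces in f_Pi, reduced energies in units of 2*pi*kappa.  The
# equilibrium problem is solved by shooting from the apex: unknowns are the
# apex curvature u0, the apical force ftil (when the height is imposed) and
# the total arclength Sigma (a free boundary).  Boundary conditions at the
# contact line: psi = 0, the detachment (curvature-jump) condition, and (in
# height mode) h = L.  The free-arclength first integral fixes nu(0) = 0 and
# the point force enters as the constant axial multiplier.
#
# For shapes with narrow necks single shooting becomes ill-conditioned, so
# the solver supports K-segment multiple shooting: the unknown vector is
# extended by the full 7-component state (psi, r, h, M, nu, a, mu) at each
# interior junction, with matching continuity residuals.

# Apex series cutoff.  With the anisotropic (BAR) term the apex has a
# power-law mode ~ s^(Gam/2) instead of the point-force logarithm; a larger
# cutoff keeps shooting well conditioned there.
.eps_of <- function(nd) {
  if (nd$Gam > 0.05) min(5e-3, max(1e-6, 30^(-2 / nd$Gam))) else 1e-6
}

.theta_layout <- function(nd, K, fmode = FALSE) {
  het <- isTRUE(nd$het)
  nhead <- 2 + !fmode + het              # u0, [ftil], Sigma, [mu0]
  list(het = het, K = K, fmode = fmode, nhead = nhead,
       n = nhead + 7 * (K - 1))
}

.theta_unpack <- function(theta, lay) {
  i <- 1
  u0 <- theta[i]; i <- i + 1
  ftil <- if (!lay$fmode) { v <- theta[i]; i <- i + 1; v } else attr(theta, "ftil")
  Sigma <- theta[i]; i <- i + 1
  mu0 <- if (lay$het) { v <- theta[i]; i <- i + 1; v } else 0
  ymid <- if (lay$K > 1)
    matrix(theta[i:(i + 7 * (lay$K - 1) - 1)], nrow = 7) else NULL
  list(u0 = u0, ftil = ftil, Sigma = Sigma, mu0 = mu0, ymid = ymid)
}

# K-segment shooting residual.  tau: interior split fractions (length K-1).
.shoot_k <- function(theta, nd, L = NULL, K = 1, tau = NULL, nper = 300) {
  lay <- .theta_layout(nd, K, fmode = is.null(L))
  up <- .theta_unpack(theta, lay)
  if (!is.finite(up$Sigma) || up$Sigma < 0.05 || up$Sigma > 80) return(NULL)
  eps <- .eps_of(nd)
  if (K == 1) {
    out <- shape_integrate_cpp(up$u0, up$ftil, up$Sigma, up$mu0, nd,
                               nper = nper, eps = eps)
    if (!isTRUE(out$ok)) return(NULL)
    fin <- out$final
    cres <- NULL
  } else {
    if (is.null(tau)) tau <- seq_len(K - 1) / K
    sb <- c(0, tau, 1) * up$Sigma
    out1 <- shape_integrate_cpp(up$u0, up$ftil, sb[2], up$mu0, nd,
                                nper = nper, eps = eps)
    if (!isTRUE(out1$ok)) return(NULL)
    cres <- numeric(0)
    prev <- out1
    neck <- if (out1$neck >= 0) out1$neck else Inf
    for (j in seq_len(K - 1)) {
      cres <- c(cres, prev$final[1:7] - up$ymid[, j])
      y0 <- c(up$ymid[, j], prev$final[8:10], 0)
      seg <- shape_integrate_from_cpp(y0, sb[j + 2] - sb[j + 1], up$ftil, nd,
                                      nper = nper)
      if (!isTRUE(seg$ok)) return(NULL)
      if (seg$neck >= 0) neck <- min(neck, seg$neck)
      prev <- seg
    }
    out <- prev
    out$neck <- if (is.finite(neck)) neck else -1
    fin <- out$final
  }
  # detachment: the membrane leaves the wall curving away from it, with a
  # meridional-curvature jump balancing the effective adhesion of the flat
  # detached membrane (negative in the apex-to-base orientation)
  u_c <- -sqrt(nd$c0^2 + 2 * nd$sig / out$kap_end)
  res <- c(fin[1], out$u_end - u_c, if (!is.null(L)) fin[3] - L,
           if (lay$het) fin[7], cres)
  list(res = res, out = out, u0 = up$u0, ftil = up$ftil, Sigma = up$Sigma,
       mu0 = up$mu0, K = K, tau = tau, theta = theta)
}

# damped Newton with finite-difference Jacobian on an arbitrary residual map
.newton_fd <- function(resfun, theta0, tol = 1e-9, maxit = 40, step_cap = 1.5) {
  theta <- theta0
  cur <- resfun(theta)
  if (is.null(cur)) return(list(converged = FALSE, reason = "bad start"))
  for (it in seq_len(maxit)) {
    nr <- sqrt(sum(cur$res^2))
    if (max(abs(cur$res)) < tol)
      return(list(converged = TRUE, theta = theta, shoot = cur, iter = it))
    n <- length(theta)
    J <- matrix(0, length(cur$res), n)
    for (j in seq_len(n)) {
      dstep <- 1e-6 * max(abs(theta[j]), 0.05)
      tp <- theta; tp[j] <- tp[j] + dstep
      sp <- resfun(tp)
      if (is.null(sp)) {
        tp[j] <- theta[j] - dstep; sp <- resfun(tp)
        if (is.null(sp)) return(list(converged = FALSE, reason = "jacobian"))
        J[, j] <- (cur$res - sp$res) / dstep
      } else J[, j] <- (sp$res - cur$res) / dstep
    }
    step <- tryCatch(solve(J, -cur$res), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step)))
      return(list(converged = FALSE, reason = "singular jacobian"))
    smax <- max(abs(step))
    if (smax > step_cap) step <- step * (step_cap / smax)
    alpha <- 1; ok <- FALSE
    for (k in 1:9) {
      tn <- theta + alpha * step
      attributes(tn) <- attributes(theta)
      sn <- resfun(tn)
      if (!is.null(sn) && all(is.finite(sn$res)) &&
          sqrt(sum(sn$res^2)) < (1 - 0.25 * alpha) * nr + 1e-14) {
        theta <- tn; cur <- sn; ok <- TRUE; break
      }
      alpha <- alpha / 2
    }
    if (!ok) return(list(converged = FALSE, reason = "line search",
                         theta = theta, shoot = cur))
  }
  list(converged = FALSE, reason = "max iterations", theta = theta, shoot = cur)
}

.newton_shoot <- function(theta0, nd, L = NULL, ftil = NULL, K = 1,
                          tau = NULL, tol = 1e-9, maxit = 40, nper = 300) {
  if (is.null(L)) attr(theta0, "ftil") <- ftil
  .newton_fd(function(th) .shoot_k(th, nd, L = L, K = K, tau = tau,
                                   nper = nper),
             theta0, tol = tol, maxit = maxit)
}

# cylinder-capped-by-hemisphere / shallow-dome tangent-angle seed for the
# direct minimizer (arclength fractions -> psi values)
.seed_psi <- function(L, N, rho = 1) {
  rim <- 1.4
  if (L > rho + rim + 0.3) {
    s_cap <- pi / 2 * rho
    s_cyl <- L - rho - rim
    s_rim <- pi / 2 * rim
    Sigma <- s_cap + s_cyl + s_rim + 1.2   # trailing flat skirt
    sg <- seq(0, Sigma, length.out = N + 1)
    psi <- ifelse(sg < s_cap, sg / rho,
           ifelse(sg < s_cap + s_cyl, pi / 2,
           ifelse(sg < s_cap + s_cyl + s_rim,
                  pi / 2 * (1 - (sg - s_cap - s_cyl) / s_rim), 0)))
  } else {
    Sigma <- max(2.8, 2.2 * L + 1.5)
    tt <- seq(0, 1, length.out = N + 1)
    base <- sin(pi * tt)^2
    hgt <- function(A) sum(sin(A * base[-1]) * Sigma / N)
    A <- tryCatch(stats::uniroot(function(A) hgt(A) - L, c(1e-4, 2.4))$root,
                  error = function(e) min(2.2, 2.5 * L / Sigma * pi))
    psi <- A * base
  }
  list(psi = psi, Sigma = Sigma)
}

# Direct augmented-Lagrangian minimization of the discretized energy at fixed
# height; independent of the shooting path.
.minimize_nd <- function(nd, L, N = 150, psi_init = NULL, Sigma_init = NULL,
                         outer = 8, pen0 = 50, lam0 = 1) {
  levels <- if (is.null(psi_init) && N > 80) c(60, N) else N
  if (is.null(psi_init)) {
    sd0 <- .seed_psi(L, levels[1])
    psi_init <- sd0$psi; Sigma_init <- sd0$Sigma
  } else if (length(psi_init) != levels[1] + 1) {
    psi_init <- stats::approx(seq(0, 1, length.out = length(psi_init)),
                              psi_init, seq(0, 1, length.out = levels[1] + 1))$y
  }
  SigU <- max(12, L + 6)
  lam <- lam0
  psi <- psi_init; Sigma <- Sigma_init
  for (Nl in levels) {
    if (length(psi) != Nl + 1)
      psi <- stats::approx(seq(0, 1, length.out = length(psi)), psi,
                           seq(0, 1, length.out = Nl + 1))$y
    psi[1] <- 0; psi[Nl + 1] <- 0
    x <- c(psi[2:Nl], Sigma)
    pen <- pen0
    for (k in seq_len(outer)) {
      op <- stats::optim(x, fn = al_objective_cpp, gr = al_gradient_cpp,
                         pars = nd, L = L, lam = lam, pen = pen,
                         method = "L-BFGS-B",
                         lower = c(rep(-0.6, Nl - 1), 0.4),
                         upper = c(rep(pi + 0.6, Nl - 1), SigU),
                         control = list(maxit = 2000, factr = 1e4))
      x <- op$par
      comp <- discrete_energy_cpp(x, nd)
      cviol <- comp[["height"]] - L
      lam <- lam + pen * cviol
      if (abs(cviol) < 1e-7 && k >= 2) break
      pen <- min(pen * 3, 3000)
    }
    psi <- c(0, x[1:(Nl - 1)], 0)
    Sigma <- x[Nl]
  }
  comp <- discrete_energy_cpp(c(psi[2:N], Sigma), nd)
  list(psi = psi, Sigma = Sigma, lam = lam, E = comp[["E"]],
       height = comp[["height"]], comp = comp, N = N,
       converged = abs(comp[["height"]] - L) < 1e-4)
}

# reconstruct (s, r, z) from minimizer psi nodes
.minimizer_profile <- function(mn) {
  N <- mn$N
  h <- mn$Sigma / N
  s <- seq(0, mn$Sigma, length.out = N + 1)
  cmid <- cos((mn$psi[-1] + mn$psi[-(N + 1)]) / 2)
  smid <- sin((mn$psi[-1] + mn$psi[-(N + 1)]) / 2)
  r <- c(0, cumsum(cmid * h))
  depth <- c(0, cumsum(smid * h))
  data.frame(s = s, r = r, z = mn$height - depth, psi = mn$psi)
}

# Solve in nondimensional form.  `guess` is either NULL (cold start seeded by
# the direct minimizer) or a list with u0, ftil, Sigma, mu0 and optionally
# K, tau, theta (full multiple-shooting state of a nearby solution).
.solve_nd <- function(nd, L = NULL, ftil = NULL, guess = NULL, nper = 300,
                      cold_N = 120, allow_ms = TRUE) {
  het <- isTRUE(nd$het)
  run <- function(g) {
    K <- if (!is.null(g$K)) g$K else 1L
    tau <- g$tau
    if (!is.null(g$theta) && !is.null(L)) theta0 <- g$theta
    else {
      mu0g <- if (is.null(g$mu0)) 0 else g$mu0
      theta0 <- c(g$u0, if (!is.null(L)) g$ftil, g$Sigma, if (het) mu0g)
      if (K > 1) {
        ym <- if (!is.null(g$ymid)) as.vector(g$ymid)
              else utils::tail(g$theta, 7 * (K - 1))
        theta0 <- c(theta0, ym)
      }
    }
    .newton_shoot(theta0, nd, L = L, ftil = ftil, K = K, tau = tau,
                  nper = nper)
  }
  nw <- list(converged = FALSE)
  if (!is.null(guess)) {
    nw <- run(guess)
    Kused <- if (!is.null(guess$K)) guess$K else 1L
    tauused <- guess$tau
  } else {
    mn <- .minimize_nd(nd, if (is.null(L)) 3 else L, N = cold_N)
    for (g in .cold_guesses(nd, if (is.null(L)) 3 else L, ftil, mn)) {
      nw <- run(g); Kused <- 1L; tauused <- NULL
      if (isTRUE(nw$converged)) break
    }
    if (!isTRUE(nw$converged) && allow_ms && !is.null(L)) {
      for (g in .cold_guesses_ms(nd, L, ftil, mn)) {
        nw <- run(g); Kused <- g$K; tauused <- g$tau
        if (isTRUE(nw$converged)) break
      }
    }
  }
  if (!isTRUE(nw$converged)) return(list(converged = FALSE, newton = nw))
  sh <- nw$shoot
  list(converged = TRUE, u0 = sh$u0, ftil = sh$ftil, Sigma = sh$Sigma,
       mu0 = sh$mu0, K = sh$K, tau = sh$tau, theta = nw$theta,
       L = sh$out$final[3], final = sh$out$final,
       neck = if (sh$out$neck >= 0) sh$out$neck else NA_real_,
       residual = max(abs(sh$res)), H_end = sh$out$final[11],
       iter = nw$iter)
}

# single-shooting cold candidates from a direct minimization
.cold_guesses <- function(nd, L, ftil, mn) {
  pr <- .minimizer_profile(mn)
  depth <- mn$height - pr$z
  live <- which(abs(pr$psi) > 0.04 | depth < mn$height - 0.04)
  Sg <- if (length(live)) min(pr$s[max(live)] + 0.8, mn$Sigma) else mn$Sigma
  near <- which(pr$s > 0 & pr$s < 0.6)
  slope <- if (length(near) >= 2)
    sum(pr$psi[near] * pr$s[near]) / sum(pr$s[near]^2)
  else mn$psi[2] / (mn$Sigma / mn$N)
  u_c <- sqrt(nd$c0^2 + 2 * nd$sig + nd$Gam * nd$rho0inv^2)
  fcand <- if (!is.null(ftil)) ftil else
    unique(c(max(min(mn$lam, 3), -1), 0.75, 2 * nd$c0, 2 * u_c,
             0.75 + 1.5 * nd$c0, 1.5))
  # the point force gives the apex curvature a logarithmic boost between the
  # macroscopic scale and the series cutoff (Gamma = 0); with the BAR term
  # the apex curvature is pinned near rho0inv + ftil/Gamma instead
  cand <- list()
  for (fc in fcand) {
    u0c <- if (nd$Gam > 0.05)
      unique(c(nd$rho0inv + fc / nd$Gam, slope,
               0.8 * (nd$rho0inv + fc / nd$Gam)))
    else
      unique(c(slope + fc / 2 * log(c(0.03, 0.1, 0.3) / 1e-6), slope))
    for (u0 in u0c) cand[[length(cand) + 1]] <-
      list(u0 = u0, ftil = fc, Sigma = Sg, mu0 = 0)
  }
  score <- vapply(cand, function(g) {
    sh <- .shoot_k(c(g$u0, g$ftil, g$Sigma, if (isTRUE(nd$het)) 0), nd, L = L)
    if (is.null(sh)) Inf else sqrt(sum(sh$res^2))
  }, numeric(1))
  cand[utils::head(order(score), 6)]
}

# two-segment multiple-shooting candidates: junction state read off the
# minimizer profile, split placed at the neck when one exists
.cold_guesses_ms <- function(nd, L, ftil, mn) {
  pr <- .minimizer_profile(mn)
  N <- mn$N
  depth <- mn$height - pr$z
  live <- which(abs(pr$psi) > 0.04 | depth < mn$height - 0.04)
  Sg <- if (length(live)) min(pr$s[max(live)] + 0.8, mn$Sigma) else mn$Sigma
  near <- which(pr$s > 0 & pr$s < 0.6)
  slope <- if (length(near) >= 2)
    sum(pr$psi[near] * pr$s[near]) / sum(pr$s[near]^2)
  else mn$psi[2] / (mn$Sigma / mn$N)
  # neck position from the profile restricted to the live part
  ilive <- pr$s <= Sg
  r <- pr$r[ilive]; s <- pr$s[ilive]
  imax <- which.max(r)
  tau0 <- if (imax < length(r) - 3) {
    ineck <- imax - 1 + which.min(r[imax:length(r)])
    min(max(s[ineck] / Sg, 0.3), 0.85)
  } else 0.55
  hstep <- mn$Sigma / N
  u_n <- c(diff(mn$psi) / hstep, 0)
  ymid_at <- function(tau) {
    sm <- tau * Sg
    ix <- which.min(abs(pr$s - sm))
    w <- u_n[ix] + sin(pr$psi[ix]) / max(pr$r[ix], 1e-6) - nd$c0
    c(pr$psi[ix], max(pr$r[ix], 1e-4), depth[ix], pr$r[ix] * w, 0, 0, 0)
  }
  fcand <- if (!is.null(ftil)) ftil else
    unique(c(max(min(mn$lam, 3), -1), 0.3, 0.75, 2 * nd$c0))
  cand <- list()
  for (fc in fcand) {
    for (u0 in unique(c(slope + fc / 2 * log(c(0.03, 0.2) / 1e-6), slope))) {
      ym <- ymid_at(tau0)
      # accumulated area at junction not tracked by the minimizer; estimate
      ym[6] <- sum(pr$r[pr$s <= tau0 * Sg]) * hstep
      cand[[length(cand) + 1]] <-
        list(u0 = u0, ftil = fc, Sigma = Sg, mu0 = 0, K = 2L, tau = tau0,
             ymid = matrix(ym, ncol = 1))
    }
  }
  cand
}

# interior neck radius from a trajectory matrix
.neck_from_traj <- function(traj) {
  r <- traj[, "r"]
  n <- length(r)
  if (n < 5) return(NA_real_)
  dm <- diff(sign(diff(r)))
  idx <- which(dm > 0) + 1
  idx <- idx[idx > 2 & idx < n]
  if (length(idx)) min(r[idx]) else NA_real_
}

# full trajectory of a converged solution (any K)
.full_traj <- function(sol, nd, nper = 300) {
  K <- if (is.null(sol$K)) 1L else sol$K
  eps <- .eps_of(nd)
  if (K == 1) {
    out <- shape_integrate_cpp(sol$u0, sol$ftil, sol$Sigma, sol$mu0, nd,
                               nper = nper, traj = TRUE, eps = eps)
    return(out)
  }
  lay <- .theta_layout(nd, K)
  up <- .theta_unpack(sol$theta, lay)
  sb <- c(0, sol$tau, 1) * up$Sigma
  out1 <- shape_integrate_cpp(up$u0, up$ftil, sb[2], up$mu0, nd,
                              nper = nper, traj = TRUE, eps = eps)
  trajs <- list(out1$traj)
  prev <- out1
  for (j in seq_len(K - 1)) {
    y0 <- c(up$ymid[, j], prev$final[8:10], 0)
    seg <- shape_integrate_from_cpp(y0, sb[j + 2] - sb[j + 1], up$ftil, nd,
                                    nper = nper, traj = TRUE,
                                    s_offset = sb[j + 1])
    trajs[[j + 1]] <- seg$traj[-1, , drop = FALSE]
    prev <- seg
  }
  prev$traj <- do.call(rbind, trajs)
  prev
}

# assemble a physical shape_solution from a converged nondimensional solve
.make_solution <- function(nd, params, sol, nper = 300, het_spec = NULL) {
  sc <- derived_scales(params)
  out <- .full_traj(sol, nd, nper = nper)
  traj <- out$traj
  Lnd <- out$final[3]
  prof <- shape_profile(s = traj[, "s"] * sc$R_Pi,
                        r = traj[, "r"] * sc$R_Pi,
                        z = pmax(Lnd - traj[, "h"], 0) * sc$R_Pi,
                        psi = traj[, "psi"], check = FALSE)
  fin <- out$final
  twoPik <- 2 * pi * params$kappa
  energies <- list(
    E_bend = twoPik * fin[8],
    E_tension = twoPik * nd$sig * fin[6],
    E_pressure = twoPik * fin[10] / 2,
    E_bar = twoPik * fin[9],
    # uniform BAR coverage: flat-coated-state reference over the projected
    # contact disk (0 unless Gamma > 0)
    E_bar_ref = -twoPik * nd$Gam * nd$rho0inv^2 / 2 * fin[2]^2 / 2,
    work = -sol$ftil * sc$f_Pi * Lnd * sc$R_Pi)
  energies$F_total <- energies$E_bend + energies$E_tension +
    energies$E_pressure + energies$E_bar + energies$E_bar_ref +
    energies$work
  energies$E_deform <- energies$F_total - energies$work
  class(energies) <- "energy_breakdown"
  observables <- list(
    L = Lnd * sc$R_Pi,
    V = 2 * pi * fin[10] * sc$R_Pi^3,
    S = 2 * pi * fin[6] * sc$R_Pi^2,
    S0 = pi * (fin[2] * sc$R_Pi)^2,
    neck_radius = .neck_from_traj(traj) * sc$R_Pi,
    tip_radius = sc$R_Pi / sol$u0)
  structure(list(
    profile = prof, params = params, f_a = sol$ftil * sc$f_Pi,
    L = Lnd * sc$R_Pi, observables = observables, energies = energies,
    residual = sol$residual, converged = TRUE,
    nondim = list(u0 = sol$u0, ftil = sol$ftil, Sigma = sol$Sigma,
                  mu0 = sol$mu0, K = sol$K, tau = sol$tau, theta = sol$theta,
                  L = Lnd, c0 = nd$c0, sig = nd$sig,
                  Gam = nd$Gam, rho0inv = nd$rho0inv, H_end = sol$H_end,
                  neck = sol$neck),
    rigidity = het_spec), class = "shape_solution")
}

.no_equilibrium <- function(msg, diagnostics = NULL) {
  cond <- structure(class = c("endomech_no_equilibrium", "error", "condition"),
                    list(message = msg, call = sys.call(-1),
                         diagnostics = diagnostics))
  stop(cond)
}

.solver_failure <- function(msg, diagnostics = NULL) {
  cond <- structure(class = c("endomech_solver_failure", "error", "condition"),
                    list(message = msg, call = sys.call(-1),
                         diagnostics = diagnostics))
  stop(cond)
}

# Robust cold start: direct solve, then walks in L from anchor heights that
# usually converge, then a walk in spontaneous curvature from a value below
# the instability thresholds.  Returns NULL when everything fails.
.solve_anchor <- function(nd, L, c0_floor = 0.35) {
  sol <- .solve_nd(nd, L = L)
  if (sol$converged) return(sol)
  for (Lalt in c(0.3, 0.5, 1, 2, 4)) {
    if (abs(Lalt - L) < 1e-9) next
    s0 <- .solve_nd(nd, L = Lalt)
    if (!s0$converged) next
    wk <- .walk_to_from(nd, s0, to = L)
    if (wk$reached) return(wk$sol)
  }
  if (nd$c0 > c0_floor + 1e-9) {
    nd_lo <- nd; nd_lo$c0 <- c0_floor
    s0 <- .solve_anchor(nd_lo, L, c0_floor = c0_floor)
    if (!is.null(s0)) {
      wk <- .walk_c0(nd_lo, s0, c0_to = nd$c0, L = L)
      if (wk$reached) return(wk$sol)
    }
  }
  NULL
}

# warm-started walk in L from an existing solution
.walk_to_from <- function(nd, sol, to, max_steps = 60) {
  Lcur <- sol$L
  step <- sign(to - Lcur) * min(0.4, abs(to - Lcur))
  if (step == 0) return(list(reached = TRUE, sol = sol))
  for (k in seq_len(max_steps)) {
    Lnext <- if (step > 0) min(Lcur + step, to) else max(Lcur + step, to)
    nxt <- .solve_nd(nd, L = Lnext, guess = sol)
    if (nxt$converged) {
      sol <- nxt; Lcur <- Lnext
      if (abs(Lcur - to) < 1e-12) return(list(reached = TRUE, sol = sol))
      step <- sign(to - Lcur) * min(abs(step) * 1.5, 0.5)
    } else {
      step <- step / 2
      if (abs(step) < 1e-3) return(list(reached = FALSE, L_last = Lcur,
                                        sol = sol))
    }
  }
  list(reached = FALSE, L_last = Lcur, sol = sol)
}

# warm-started walk in spontaneous curvature at fixed height; upgrades to
# two-segment shooting when single shooting stalls at a narrow neck
.walk_c0 <- function(nd, sol, c0_to, L, max_steps = 80) {
  c0cur <- nd$c0
  step <- sign(c0_to - c0cur) * min(0.05, abs(c0_to - c0cur))
  upgraded <- !is.null(sol$K) && sol$K > 1
  for (k in seq_len(max_steps)) {
    c0next <- if (step > 0) min(c0cur + step, c0_to) else max(c0cur + step, c0_to)
    ndn <- nd; ndn$c0 <- c0next
    nxt <- .solve_nd(ndn, L = L, guess = sol)
    if (nxt$converged) {
      sol <- nxt; c0cur <- c0next
      if (abs(c0cur - c0_to) < 1e-12) return(list(reached = TRUE, sol = sol))
      step <- sign(c0_to - c0cur) * min(abs(step) * 1.5, 0.08)
    } else {
      if (!upgraded && abs(step) < 5e-3) {
        ndc <- nd; ndc$c0 <- c0cur
        up <- .upgrade_to_ms(ndc, sol)
        if (!is.null(up)) { sol <- up; upgraded <- TRUE; next }
      }
      step <- step / 2
      if (abs(step) < 2e-4) return(list(reached = FALSE, c0_last = c0cur,
                                        sol = sol))
    }
  }
  list(reached = FALSE, c0_last = c0cur, sol = sol)
}

# re-represent a converged single-shooting solution as a two-segment
# multiple-shooting solution, split at the neck
.upgrade_to_ms <- function(nd, sol, nper = 300) {
  if (!is.null(sol$K) && sol$K > 1) return(sol)
  out <- .full_traj(sol, nd, nper = nper)
  traj <- out$traj
  r <- traj[, "r"]
  imax <- which.max(r)
  ineck <- if (imax < nrow(traj) - 3)
    imax - 1 + which.min(r[imax:nrow(traj)]) else round(nrow(traj) * 0.55)
  tau <- min(max(traj[ineck, "s"] / sol$Sigma, 0.25), 0.85)
  ix <- which.min(abs(traj[, "s"] - tau * sol$Sigma))
  ymid <- traj[ix, c("psi", "r", "h", "M", "nu", "a", "mu")]
  theta0 <- c(sol$u0, sol$ftil, sol$Sigma,
              if (isTRUE(nd$het)) sol$mu0, as.numeric(ymid))
  nw <- .newton_shoot(theta0, nd, L = sol$L, K = 2L, tau = tau, nper = nper)
  if (!isTRUE(nw$converged)) return(NULL)
  sh <- nw$shoot
  list(converged = TRUE, u0 = sh$u0, ftil = sh$ftil, Sigma = sh$Sigma,
       mu0 = sh$mu0, K = 2L, tau = tau, theta = nw$theta,
       L = sh$out$final[3], final = sh$out$final,
       neck = if (sh$out$neck >= 0) sh$out$neck else NA_real_,
       residual = max(abs(sh$res)), H_end = sh$out$final[11])
}

# Homotopy fallback for cold targets: walk the branch up from small L and, if
# it folds below the target, down from a long-tube seed; if both fold short of
# the target the height lies in a no-equilibrium gap.
.solve_target_homotopy <- function(nd, Lnd, max_steps = 40) {
  up <- .walk_to(nd, from = 0.15, to = Lnd, max_steps = max_steps)
  if (up$reached) return(up$sol)
  dn <- .walk_to(nd, from = max(6, Lnd + 2), to = Lnd, max_steps = max_steps)
  if (dn$reached) return(dn$sol)
  list(converged = FALSE, reason = "no_equilibrium",
       L_lo = up$L_last, L_hi = dn$L_last)
}

.walk_to <- function(nd, from, to, max_steps = 40) {
  sol <- .solve_anchor(nd, from)
  if (is.null(sol)) return(list(reached = FALSE, L_last = NA_real_))
  .walk_to_from(nd, sol, to, max_steps = max_steps)
}

#' Solve the equilibrium invagination shape
#'
#' Solves the Euler--Lagrange boundary-value problem of the pressurized
#' Helfrich membrane pulled by an apical point force, by shooting from the
#' apex with the total arclength as a free boundary (multiple shooting
#' through narrow necks).  Boundary conditions: apex regularity (`r` = 0
#' with point-force balance) and, at the free contact radius, `z = 0`,
#' `psi = 0` and the detachment condition — a meridional-curvature jump
#' `dpsi/ds = sqrt(C0^2 + (2 sigma + Gamma/R0^2)/kappa)` balancing the
#' effective adhesion of the flat detached membrane (see the package
#' vignette); it reduces to curvature continuity when `C0`, `sigma` and
#' `Gamma` all vanish.
#'
#' Exactly one of `L` (target height) or `f_a` (imposed apical force) must be
#' given; the other is returned as the conjugate quantity.
#'
#' @param params a [model_params].
#' @param L target invagination height \[nm\].
#' @param f_a imposed apical force \[pN\].
#' @param guess optional warm-start list with nondimensional entries
#'   `u0`, `ftil`, `Sigma` (and `mu0`, `K`, `tau`, `theta`), e.g. the
#'   `$nondim` field of a nearby solution.
#' @param nper grid density of the returned profile (nodes per `R_Pi`).
#' @param max_homotopy number of homotopy steps attempted from a cold start
#'   before declaring failure.
#' @return a `shape_solution`: list with the discretized `profile`
#'   ([shape_profile]), apical force `f_a` \[pN\], height `L`, geometric
#'   `observables`, `energies` breakdown, solver `residual` and `converged`
#'   flag, and the `nondim` solver state.
#' @seealso [trace_branch()], [direct_minimization()]
#' @export
solve_shape <- function(params, L = NULL, f_a = NULL, guess = NULL,
                        nper = 300, max_homotopy = 40) {
  stopifnot(inherits(params, "model_params"))
  if (is.null(L) == is.null(f_a))
    stop("give exactly one of 'L' or 'f_a'")
  nd <- nondim_params(params)
  sc <- derived_scales(params)
  if (!is.null(L)) {
    Lnd <- L / sc$R_Pi
    sol <- .solve_nd(nd, L = Lnd, guess = guess)
    if (!sol$converged && !is.null(guess))
      sol <- .solve_nd(nd, L = Lnd)          # cold retry after a bad guess
    if (!sol$converged) {
      alt <- .solve_anchor(nd, Lnd)
      sol <- if (!is.null(alt)) alt else
        .solve_target_homotopy(nd, Lnd, max_steps = max_homotopy)
    }
    if (!sol$converged) {
      if (identical(sol$reason, "no_equilibrium"))
        .no_equilibrium(sprintf(
          "no equilibrium shape at L = %.3g nm (%.3g R_Pi): branches end near L = %.3g and %.3g R_Pi",
          L, Lnd, sol$L_lo, sol$L_hi), sol)
      .solver_failure("shape solver failed to converge", sol)
    }
    if (!is.null(sol$neck) && !is.na(sol$neck) && sol$neck < 1e-2)
      .no_equilibrium(sprintf(
        "no open-neck equilibrium at L = %.3g nm: neck radius %.2g R_Pi is below the closure threshold",
        L, sol$neck), sol)
  } else {
    sol <- .solve_nd(nd, ftil = f_a / sc$f_Pi, guess = guess)
    if (!sol$converged) .solver_failure("shape solver failed to converge", sol)
  }
  .make_solution(nd, params, sol, nper = nper)
}

#' Direct energy-minimization oracle
#'
#' Independent check on the boundary-value solver: minimizes the discretized
#' invagination energy over tangent-angle profiles at fixed height, using
#' augmented-Lagrangian L-BFGS-B.  Shares no code path with the shooting
#' solver (different discretization, different unknowns), so agreement of the
#' two is a genuine cross-validation.
#'
#' @param params a [model_params].
#' @param L fixed invagination height \[nm\].
#' @param n_nodes number of arclength intervals of the discretization
#'   (at least 100).
#' @param psi_init,Sigma_init optional initial tangent-angle profile (values
#'   at the `n_nodes + 1` nodes) and total arclength \[units `R_Pi`\].
#' @param fd_force also estimate the apical force by central finite
#'   differences of the minimal energy in `L` (two extra minimizations);
#'   otherwise the height-constraint multiplier is used.
#' @return list with the `profile` ([shape_profile]), minimal energies,
#'   estimated apical force `f_a` \[pN\] and convergence information.
#' @export
direct_minimization <- function(params, L, n_nodes = 150, psi_init = NULL,
                                Sigma_init = NULL, fd_force = FALSE) {
  stopifnot(inherits(params, "model_params"), n_nodes >= 100)
  nd <- nondim_params(params)
  sc <- derived_scales(params)
  Lnd <- L / sc$R_Pi
  mn <- .minimize_nd(nd, Lnd, N = n_nodes, psi_init = psi_init,
                     Sigma_init = Sigma_init)
  if (!mn$converged)
    .solver_failure("direct minimization failed to satisfy height constraint")
  pr_nd <- .minimizer_profile(mn)
  prof <- shape_profile(s = pr_nd$s * sc$R_Pi, r = pr_nd$r * sc$R_Pi,
                        z = pmax(pr_nd$z, 0) * sc$R_Pi, psi = pr_nd$psi,
                        check = FALSE)
  ftil <- mn$lam
  if (fd_force) {
    dL <- 0.02
    mp <- .minimize_nd(nd, Lnd + dL, N = n_nodes, psi_init = mn$psi,
                       Sigma_init = mn$Sigma)
    mm <- .minimize_nd(nd, Lnd - dL, N = n_nodes, psi_init = mn$psi,
                       Sigma_init = mn$Sigma)
    ftil <- (mp$E - mm$E) / (2 * dL)
  }
  list(profile = prof, params = params, L = L,
       E_deform = 2 * pi * params$kappa * mn$E,
       f_a = ftil * sc$f_Pi,
       nondim = list(E = mn$E, lam = mn$lam, Sigma = mn$Sigma,
                     psi = mn$psi, N = mn$N),
       converged = mn$converged)
}

#' @export
print.shape_solution <- function(x, ...) {
  sc <- derived_scales(x$params)
  cat("Equilibrium invagination shape\n")
  cat(sprintf("  L = %.2f nm (%.3f R_Pi)   f_a = %.1f pN (%.4f f_Pi)\n",
              x$L, x$L / sc$R_Pi, x$f_a, x$f_a / sc$f_Pi))
  ob <- x$observables
  cat(sprintf("  V = %.3g nm^3, S = %.3g nm^2, tip radius = %.2f nm\n",
              ob$V, ob$S, ob$tip_radius))
  if (is.finite(ob$neck_radius) && !is.na(ob$neck_radius))
    cat(sprintf("  neck radius = %.2f nm\n", ob$neck_radius))
  cat(sprintf("  E_deform = %.1f pN nm; BVP residual %.2e\n",
              x$energies$E_deform, x$residual))
  invisible(x)
}

#' @export
plot.shape_solution <- function(x, mirror = TRUE, ...) {
  pr <- x$profile
  xlim <- c(if (mirror) -max(pr$r) else 0, max(pr$r))
  plot(pr$r, pr$z, type = "l", asp = 1, xlim = xlim,
       xlab = "r [nm]", ylab = "z [nm]", ...)
  if (mirror) graphics::lines(-pr$r, pr$z)
  graphics::abline(h = 0, col = "grey70", lty = 2)
  invisible(x)
}

#' @export
summary.shape_solution <- function(object, ...) {
  print(object)
  print(object$energies)
  invisible(object)
}
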