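# Pseudo-arclength continuation of equilibrium branches in the (L, f_a)
# plane.  The extended unknown vector is Y = (theta, L), where theta is the
# shooting vector (single or multiple shooting); the shooting residuals are
# augmented by a weighted secant-tangent normalization, which carries the
# branch through folds where L reverses.  When the neck tightens the
# representation is upgraded to two-segment shooting on the fly.

.cont_weights <- function(nd, K) {
  het <- isTRUE(nd$het)
  c(0.25, 1, 0.15, if (het) 0.25, rep(0.12, 7 * (K - 1)), 1)
}

.Yres_cont <- function(Y, nd, K, tau, tW, Yp) {
  n <- length(Y)
  sh <- .shoot_k(Y[-n], nd, L = Y[n], K = K, tau = tau)
  if (is.null(sh)) return(NULL)
  list(res = c(sh$res, sum(tW * (Y - Yp))), shoot = sh)
}

.newton_cont <- function(Y0, nd, K, tau, tW, Yp, tol = 1e-9, maxit = 14) {
  r <- .newton_fd(function(Y) .Yres_cont(Y, nd, K, tau, tW, Yp),
                  Y0, tol = tol, maxit = maxit, step_cap = 1)
  if (!is.null(r$shoot)) r$shoot <- r$shoot$shoot
  r
}

.sol_to_Y <- function(p) c(p$theta, p$L)

.sol_of_shoot <- function(sh) {
  list(converged = TRUE, u0 = sh$u0, ftil = sh$ftil, Sigma = sh$Sigma,
       mu0 = sh$mu0, K = sh$K, tau = sh$tau, theta = sh$theta,
       L = sh$out$final[3], final = sh$out$final,
       neck = if (sh$out$neck >= 0) sh$out$neck else NA_real_,
       residual = max(abs(sh$res)), H_end = NA_real_)
}

# one continuation run from a converged start, in a given L direction
.trace_nd <- function(nd, L0, Lmax, direction = +1, ds0 = 0.05,
                      eps_closure = 1e-2, max_pts = 500, Lstop_low = 0.04,
                      fmax = 6, seed = NULL) {
  p1 <- if (!is.null(seed)) seed
        else if (isTRUE(nd$het)) .solve_nd(nd, L = L0)
        else .solve_anchor(nd, L0)
  if (is.null(p1) || !isTRUE(p1$converged)) return(NULL)
  rows <- list(); folds <- list(); closure <- FALSE
  add_row <- function(p) {
    fin <- p$final
    Ered <- fin[8] + fin[9] + nd$sig * fin[6] + fin[10] / 2 -
      nd$Gam * nd$rho0inv^2 / 2 * fin[2]^2 / 2
    nk <- p$neck; if (is.null(nk)) nk <- NA_real_
    rows[[length(rows) + 1]] <<-
      data.frame(L = p$L, f = p$ftil, E = Ered, neck = nk,
                 E_bend = fin[8], E_pres = fin[10] / 2, E_bar = fin[9],
                 u0 = p$u0, Sigma = p$Sigma)
  }
  dL <- direction * min(0.04, ds0)
  p2 <- .solve_nd(nd, L = p1$L + dL, guess = p1)
  if (!p2$converged) return(NULL)
  add_row(p1); add_row(p2)
  K <- if (is.null(p2$K)) 1L else p2$K
  tau <- p2$tau
  W <- .cont_weights(nd, K)
  Yprev <- .sol_to_Y(p1); Y <- .sol_to_Y(p2)
  ds <- ds0
  pnew <- p2
  for (k in seq_len(max_pts)) {
    # upgrade to two-segment shooting when the neck narrows
    if (K == 1 && !is.na(pnew$neck) && pnew$neck < 0.15) {
      up2 <- .upgrade_to_ms(nd, pnew)
      upp <- .upgrade_to_ms(nd, .sol_from_Y(Yprev, nd, K))
      if (!is.null(up2) && !is.null(upp) &&
          identical(length(up2$theta), length(upp$theta))) {
        upp$tau <- up2$tau
        nwp <- .newton_shoot(upp$theta, nd, L = upp$L, K = 2L, tau = up2$tau)
        if (isTRUE(nwp$converged)) {
          K <- 2L; tau <- up2$tau
          W <- .cont_weights(nd, K)
          pnew <- up2
          Yprev <- c(nwp$theta, nwp$shoot$out$final[3])
          Y <- .sol_to_Y(up2)
        }
      }
    }
    t <- (Y - Yprev) * W
    tn <- sqrt(sum(t^2))
    if (tn < 1e-14) break
    t <- t / tn
    accepted <- FALSE
    for (tries in 1:10) {
      Ypred <- Y + ds * t / W
      nc <- .newton_cont(Ypred, nd, K, tau, t * W, Ypred)
      if (isTRUE(nc$converged)) { accepted <- TRUE; break }
      ds <- ds / 2
      if (ds < 1e-3) break
    }
    if (!accepted) break
    if (nc$iter <= 4) ds <- min(ds * 1.4, 0.25)
    sh <- nc$shoot
    pnew <- .sol_of_shoot(sh)
    add_row(pnew)
    nY <- length(nc$theta)
    dL_old <- Y[length(Y)] - Yprev[length(Yprev)]
    dL_new <- nc$theta[nY] - Y[length(Y)]
    if (sign(dL_new) != 0 && sign(dL_old) != 0 &&
        sign(dL_new) != sign(dL_old))
      folds[[length(folds) + 1]] <- c(L = Y[length(Y)], f = pnew$ftil)
    Yprev <- Y; Y <- nc$theta
    if (!is.na(pnew$neck) && pnew$neck < eps_closure) { closure <- TRUE; break }
    Lcur <- Y[length(Y)]
    if (Lcur > Lmax + 0.02 || Lcur < Lstop_low) break
    if (pnew$ftil > fmax || pnew$ftil < -2) break
    if (pnew$Sigma > 60) break
  }
  pts <- do.call(rbind, rows)
  list(points = pts, folds = folds, closure = closure, last = pnew)
}

.sol_from_Y <- function(Y, nd, K) {
  n <- length(Y)
  sh <- .shoot_k(Y[-n], nd, L = Y[n], K = K)
  if (is.null(sh)) return(NULL)
  .sol_of_shoot(sh)
}

# stable/unstable flags by fold parity from the seeded (stable) end
.flag_stability <- function(pts, folds) {
  if (!nrow(pts)) return(logical(0))
  stable <- rep(TRUE, nrow(pts))
  if (length(folds)) {
    dl <- sign(diff(pts$L))
    revs <- which(diff(dl) != 0 & dl[-1] != 0) + 1
    if (length(revs)) {
      par <- 0
      seg_start <- 1
      for (i in seq_along(revs)) {
        stable[seg_start:revs[i]] <- (par %% 2 == 0)
        seg_start <- revs[i] + 1
        par <- par + 1
      }
      stable[seg_start:nrow(pts)] <- (par %% 2 == 0)
    }
  }
  stable
}

#' Trace the equilibrium force--length curve
#'
#' Pseudo-arclength continuation of the equilibrium branch(es) of the
#' invagination over a height range, seeded both from the nearly flat state
#' (small `L`) and from the long-tube asymptote, so that disconnected
#' branches in the hysteresis/gap regimes are captured.  Folds (reversals of
#' `L` along a branch) are recorded and points past a fold are flagged
#' unstable; branch ends at neck closure (`neck < eps_closure`) are marked.
#'
#' @param params a [model_params].
#' @param L_range height range \[nm\] to cover (length-2 vector); the lower
#'   end is clamped to a small positive seed height.
#' @param n_keep optional down-sampling of returned points.
#' @param ds0 initial nondimensional continuation step.
#' @param eps_closure neck-closure threshold in units of `R_Pi`.
#' @param rigidity optional [rigidity_profile] for heterogeneous rigidity.
#' @return object of class `force_length_curve`: list with `branches` (a
#'   data frame with columns `branch_id`, `L_nm`, `fa_pN`, `E_pNnm`,
#'   `neck_nm`, `stable` plus nondimensional mirrors `L_nd`, `f_nd`),
#'   `fold_points`, `closure` flags, the `params` and derived `scales`.
#' @export
trace_branch <- function(params, L_range = NULL, n_keep = NULL, ds0 = 0.05,
                         eps_closure = 1e-2, rigidity = NULL) {
  stopifnot(inherits(params, "model_params"))
  sc <- derived_scales(params)
  nd <- nondim_params(params, het = rigidity)
  if (is.null(L_range)) L_range <- c(0, 6 * sc$R_Pi)
  Lmax <- max(L_range) / sc$R_Pi
  L0 <- max(min(L_range) / sc$R_Pi, 0.1)
  br <- list()
  bot <- .trace_nd(nd, L0 = L0, Lmax = Lmax, direction = +1, ds0 = ds0,
                   eps_closure = eps_closure)
  if (!is.null(bot)) {
    bot$points$stable <- .flag_stability(bot$points, bot$folds)
    bot$points$branch_id <- 1L
    br$bottom <- bot
  }
  # top seed only needed if the bottom trace did not get to Lmax cleanly
  need_top <- is.null(bot) || max(bot$points$L) < Lmax - 0.05 ||
    length(bot$folds) > 0
  if (need_top) {
    top <- tryCatch(.trace_nd(nd, L0 = Lmax, Lmax = Lmax + 0.5,
                              direction = -1, ds0 = ds0,
                              eps_closure = eps_closure),
                    error = function(e) NULL)
    if (!is.null(top)) {
      top$points$stable <- .flag_stability(top$points, top$folds)
      top$points$branch_id <- 2L
      # drop the top branch when it merely retraces the bottom one
      if (!is.null(bot) && nrow(top$points) > 2) {
        if (!.branch_overlaps(bot$points, top$points)) br$top <- top
      } else if (is.null(bot)) br$top <- top
    }
  }
  if (!length(br)) .solver_failure("continuation failed from both seeds")
  pts <- do.call(rbind, lapply(br, function(b) b$points))
  folds <- do.call(rbind, lapply(br, function(b)
    if (length(b$folds)) do.call(rbind, b$folds)))
  if (!is.null(n_keep) && nrow(pts) > n_keep)
    pts <- pts[unique(round(seq(1, nrow(pts), length.out = n_keep))), ]
  branches <- data.frame(
    branch_id = pts$branch_id,
    L_nm = pts$L * sc$R_Pi, fa_pN = pts$f * sc$f_Pi,
    E_pNnm = pts$E * 2 * pi * params$kappa,
    neck_nm = pts$neck * sc$R_Pi,
    stable = pts$stable,
    L_nd = pts$L, f_nd = pts$f, E_nd = pts$E, neck_nd = pts$neck,
    E_bend_nd = pts$E_bend, E_pres_nd = pts$E_pres, E_bar_nd = pts$E_bar,
    u0 = pts$u0, Sigma = pts$Sigma)
  structure(list(branches = branches,
                 fold_points = if (!is.null(folds))
                   data.frame(L_nd = folds[, "L"], f_nd = folds[, "f"],
                              L_nm = folds[, "L"] * sc$R_Pi,
                              fa_pN = folds[, "f"] * sc$f_Pi)
                 else NULL,
                 closure = vapply(br, function(b) b$closure, logical(1)),
                 params = params, scales = sc, rigidity = rigidity),
            class = "force_length_curve")
}

# do two traces cover the same (L, f) curve?
.branch_overlaps <- function(a, b, tol = 2e-2) {
  Lmin <- max(min(a$L), min(b$L)); Lmax <- min(max(a$L), max(b$L))
  if (Lmax - Lmin < 0.2) return(FALSE)
  Ls <- seq(Lmin + 0.02, Lmax - 0.02, length.out = 8)
  fa <- stats::approx(a$L, a$f, Ls, ties = mean)$y
  fb <- stats::approx(b$L, b$f, Ls, ties = mean)$y
  all(abs(fa - fb) < tol * pmax(abs(fa), 0.2), na.rm = TRUE)
}

#' @export
print.force_length_curve <- function(x, ...) {
  b <- x$branches
  cat("Force-length curve:", length(unique(b$branch_id)), "branch(es),",
      nrow(b), "points\n")
  for (id in unique(b$branch_id)) {
    bi <- b[b$branch_id == id, ]
    cat(sprintf("  branch %d: L in [%.2f, %.2f] nm, f in [%.1f, %.1f] pN%s\n",
                id, min(bi$L_nm), max(bi$L_nm), min(bi$fa_pN), max(bi$fa_pN),
                if (any(!bi$stable)) " (has unstable segment)" else ""))
  }
  if (!is.null(x$fold_points))
    cat(sprintf("  %d fold point(s) at L = %s nm\n", nrow(x$fold_points),
                paste(round(x$fold_points$L_nm, 2), collapse = ", ")))
  if (any(x$closure)) cat("  branch terminates at neck closure\n")
  invisible(x)
}

#' @export
plot.force_length_curve <- function(x, nondim = TRUE, ...) {
  b <- x$branches
  if (nondim) {
    plot(b$L_nd, b$f_nd, type = "n", xlab = "L / R_Pi", ylab = "f_a / f_Pi", ...)
    for (id in unique(b$branch_id)) {
      bi <- b[b$branch_id == id, ]
      graphics::lines(bi$L_nd[bi$stable], bi$f_nd[bi$stable], col = id)
      graphics::points(bi$L_nd[!bi$stable], bi$f_nd[!bi$stable], pch = ".",
                       col = id)
    }
  } else {
    plot(b$L_nm, b$fa_pN, type = "p", pch = 20, cex = 0.4,
         xlab = "L [nm]", ylab = "f_a [pN]", ...)
  }
  invisible(x)
}
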