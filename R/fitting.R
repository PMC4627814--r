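# Rectification of traced 2D membrane contours to axisymmetric profiles and
# model-parameter fitting.

#' Traced 2D membrane contour
#'
#' An ordered polyline tracing the membrane through an invagination from the
#' wall level on one side, over the apex, to the wall level on the other
#' side (as obtained from electron-tomography slices).
#'
#' @param x,y point coordinates \[nm\]; `y` is height above the wall plane.
#' @param pixel_size optional pixel size \[nm\] stored as metadata.
#' @param seed optional generator seed stored as metadata (synthetic data).
#' @return object of class `contour2d` (data frame with columns `x`, `y`).
#' @export
contour2d <- function(x, y, pixel_size = NA_real_, seed = NA_integer_) {
  stopifnot(length(x) == length(y))
  if (length(x) < 10) stop("contour needs at least 10 points")
  ct <- data.frame(x = x, y = y)
  attr(ct, "pixel_size") <- pixel_size
  attr(ct, "seed") <- seed
  class(ct) <- c("contour2d", "data.frame")
  ct
}

#' Rectify a contour to an axisymmetric profile
#'
#' Estimates the symmetry axis (least-squares midline of left/right points
#' matched by normalized arclength from the apex), averages the left and
#' right radii, and returns an axisymmetric `(r, z)` profile sampled from
#' the apex down to the wall.  Matching by arclength rather than height
#' keeps overhanging necks (radius multivalued in height) well defined.
#'
#' @param contour a [contour2d].
#' @param n_out number of output samples along the profile.
#' @return data frame of class `rectified_profile` with columns `t`
#'   (normalized arclength from apex), `r`, `z` \[nm\]; attributes `axis_x`
#'   (estimated axis position), `asymmetry` (RMS left-right radius
#'   discrepancy, nm) and `L` (height).
#' @export
rectify_contour <- function(contour, n_out = 80) {
  stopifnot(inherits(contour, "contour2d"))
  x <- contour$x; y <- contour$y
  iap <- which.max(y)
  if (iap < 3 || iap > length(x) - 2)
    stop("rectification failure: apex at the contour boundary")
  left <- data.frame(x = x[iap:1], y = y[iap:1])          # apex -> base
  right <- data.frame(x = x[iap:length(x)], y = y[iap:length(x)])
  arcpar <- function(df) {
    s <- c(0, cumsum(sqrt(diff(df$x)^2 + diff(df$y)^2)))
    if (max(s) <= 0) stop("rectification failure: degenerate side")
    s / max(s)
  }
  tl <- arcpar(left); tr <- arcpar(right)
  tt <- seq(0, 1, length.out = n_out)
  xL <- stats::approx(tl, left$x, tt, ties = mean)$y
  yL <- stats::approx(tl, left$y, tt, ties = mean)$y
  xR <- stats::approx(tr, right$x, tt, ties = mean)$y
  yR <- stats::approx(tr, right$y, tt, ties = mean)$y
  axis_x <- mean((xL + xR) / 2)
  rL <- axis_x - xL; rR <- xR - axis_x
  if (mean(rL) < 0 && mean(rR) < 0) stop("rectification failure: sides do ",
                                         "not straddle the fitted axis")
  r <- (rL + rR) / 2
  z <- (yL + yR) / 2
  r[1] <- max(r[1], 0)
  asym <- sqrt(mean((rR - rL)^2))
  z <- z - min(z[length(z)], 0)   # base at the wall plane
  out <- data.frame(t = tt, r = pmax(r, 0), z = pmax(z, 0))
  attr(out, "axis_x") <- axis_x
  attr(out, "asymmetry") <- asym
  attr(out, "L") <- max(z) - min(z)
  class(out) <- c("rectified_profile", "data.frame")
  out
}

# --- solver cache shared across fit evaluations -----------------------------

#' @rdname fit_profile
#' @export
fit_cache <- function() new.env(parent = emptyenv())

.cache_key <- function(c0, sig) sprintf("%.5f|%.5f", c0, sig)

.cache_nearest <- function(cache, c0, sig) {
  keys <- ls(cache)
  if (!length(keys)) return(NULL)
  kv <- do.call(rbind, strsplit(keys, "|", fixed = TRUE))
  d <- (as.numeric(kv[, 1]) - c0)^2 + 4 * (as.numeric(kv[, 2]) - sig)^2
  cache[[keys[which.min(d)]]]
}

# solve (c0, sig) at height L, warm-started from the cache; returns the light
# solution list or NULL
.cached_solve <- function(cache, nd, c0, sig, L) {
  ndc <- nd; ndc$c0 <- c0; ndc$sig <- sig
  key <- .cache_key(c0, sig)
  cell <- cache[[key]]
  sol <- NULL
  if (!is.null(cell) && length(cell)) {
    Ls <- vapply(cell, function(s) s$L, numeric(1))
    near <- cell[[which.min(abs(Ls - L))]]
    if (abs(near$L - L) < 1e-9) return(near)
    sol <- tryCatch({
      s <- .solve_nd(ndc, L = L, guess = near)
      if (s$converged) s else {
        wk <- .walk_to_from(ndc, near, to = L)
        if (wk$reached) wk$sol else NULL
      }
    }, error = function(e) NULL)
  }
  if (is.null(sol)) {
    # borrow a start from the nearest neighbouring cell, else cold start
    nb <- .cache_nearest(cache, c0, sig)
    if (!is.null(nb) && length(nb)) {
      Ls <- vapply(nb, function(s) s$L, numeric(1))
      near <- nb[[which.min(abs(Ls - L))]]
      s <- tryCatch(.solve_nd(ndc, L = L, guess = near),
                    error = function(e) list(converged = FALSE))
      if (s$converged) sol <- s
    }
    if (is.null(sol)) {
      s <- tryCatch(.solve_anchor(ndc, L), error = function(e) NULL)
      if (!is.null(s) && s$converged) sol <- s
    }
  }
  if (is.null(sol) || !isTRUE(sol$converged)) return(NULL)
  cell <- c(cell, list(sol))
  if (length(cell) > 40) cell <- cell[-1]
  cache[[key]] <- cell
  sol
}

# distance from each point of A to the polyline with vertex matrix B
.pts_to_polyline <- function(A, B) {
  x1 <- B[-nrow(B), 1]; y1 <- B[-nrow(B), 2]
  dx <- diff(B[, 1]); dy <- diff(B[, 2])
  len2 <- pmax(dx^2 + dy^2, 1e-12)
  tt <- (outer(A[, 1], x1, "-") * rep(dx, each = nrow(A)) +
         outer(A[, 2], y1, "-") * rep(dy, each = nrow(A))) /
        rep(len2, each = nrow(A))
  tt <- pmin(pmax(tt, 0), 1)
  px <- rep(x1, each = nrow(A)) + tt * rep(dx, each = nrow(A))
  py <- rep(y1, each = nrow(A)) + tt * rep(dy, each = nrow(A))
  d2 <- (A[, 1] - px)^2 + (A[, 2] - py)^2
  dim(d2) <- c(nrow(A), nrow(B) - 1)
  sqrt(apply(d2, 1, min))
}

# symmetric mean closest-point distance between two ordered profiles,
# clipped just above the wall plane so unequal contact radii do not dominate
.profile_distance <- function(obs, mod, zclip = 0.5) {
  A <- obs[obs[, 2] > zclip, , drop = FALSE]
  B <- mod[mod[, 2] > zclip, , drop = FALSE]
  if (nrow(A) < 2 || nrow(B) < 2) return(Inf)
  (mean(.pts_to_polyline(A, B)) + mean(.pts_to_polyline(B, A))) / 2
}

# joint residual of one parameter point over all profiles
.fit_residual <- function(par, nd0, profs, cache, scale_mod = 250) {
  R_Pi <- par[1]; sig <- par[2]; c0 <- par[3]
  if (R_Pi < 2 || R_Pi > 60 || sig < 0 || sig > 0.6 || c0 < -0.05 ||
      c0 > 1.5) return(list(value = Inf))
  total <- 0; fs <- numeric(length(profs)); ok <- TRUE
  for (i in seq_along(profs)) {
    ob <- profs[[i]]
    Lnd <- attr(ob, "L") / R_Pi
    if (Lnd < 0.05 || Lnd > 14) return(list(value = Inf))
    sol <- .cached_solve(cache, nd0, c0, sig, Lnd)
    if (is.null(sol)) { ok <- FALSE; total <- Inf; break }
    out <- .full_traj(sol, within_nd(nd0, c0, sig))
    if (!isTRUE(out$ok)) { ok <- FALSE; total <- Inf; break }
    traj <- out$traj
    keep <- unique(round(seq(1, nrow(traj), length.out = scale_mod)))
    mod <- cbind(traj[keep, "r"] * R_Pi,
                 (sol$L - traj[keep, "h"]) * R_Pi)
    obsm <- cbind(ob$r, ob$z)
    total <- total + .profile_distance(obsm, mod)
    fs[i] <- sol$ftil
  }
  list(value = total / length(profs), f_nd = fs, feasible = ok)
}

within_nd <- function(nd, c0, sig) { nd$c0 <- c0; nd$sig <- sig; nd }

#' Fit model parameters to membrane profiles
#'
#' Fits the pressure--rigidity scale `R_Pi`, reduced tension
#' `sigma_nd = sigma R_Pi^2/kappa` and reduced spontaneous curvature
#' `c0_nd = C0 R_Pi` to one or more rectified membrane profiles, by
#' minimizing the mean symmetric closest-point distance between each
#' observed profile and the model equilibrium of equal height (whose apical
#' force is then implied).  Search: coarse grid then Nelder--Mead
#' refinement.  Parameter points in the no-equilibrium gap are infeasible
#' and excluded.  All grid points within `degeneracy_tol` times the best
#' residual form the reported degenerate set, mirroring the fact that
#' profiles constrain some parameter combinations only weakly.
#'
#' @param profiles a [rectified_profile] or list of them (or plain data
#'   frames with columns `r`, `z` and attribute `L`).
#' @param grid_R_Pi,grid_sigma,grid_c0 grid values of the three parameters
#'   (`R_Pi` in nm, the others nondimensional).
#' @param refine run Nelder--Mead refinement from the best grid point.
#' @param degeneracy_tol residual ratio defining the degenerate set.
#' @param cache a [fit_cache] reused across calls (optional, speeds up
#'   repeated fits with similar parameters).
#' @return object of class `invagination_fit`: best parameters, per-profile
#'   apical forces (nondimensional and, via [fit_report], physical),
#'   residual \[nm\], the evaluated `grid`, and the `degenerate_set`.
#' @export
fit_profile <- function(profiles,
                        grid_R_Pi = seq(5, 40, length.out = 8),
                        grid_sigma = seq(0, 0.3, length.out = 8),
                        grid_c0 = seq(0, 1, length.out = 8),
                        refine = TRUE, degeneracy_tol = 1.1,
                        cache = NULL) {
  if (inherits(profiles, "rectified_profile") || (is.data.frame(profiles) &&
      all(c("r", "z") %in% names(profiles))))
    profiles <- list(profiles)
  stopifnot(length(profiles) >= 1)
  for (p in profiles)
    if (is.null(attr(p, "L"))) attr(p, "L") <- max(p$z)
  if (is.null(cache)) cache <- fit_cache()
  nd0 <- list(c0 = 0, sig = 0, Gam = 0, rho0inv = 0, het = FALSE,
              kmin = 1, atip = 1, wa = 1)
  grid <- expand.grid(R_Pi = grid_R_Pi, sigma_nd = grid_sigma,
                      c0_nd = grid_c0)
  # evaluate cells in an order that lets warm starts flow: by (c0, sigma)
  # then descending R_Pi (ascending nondimensional height)
  ord <- order(grid$c0_nd, grid$sigma_nd, -grid$R_Pi)
  res <- rep(NA_real_, nrow(grid))
  for (i in ord) {
    r <- .fit_residual(c(grid$R_Pi[i], grid$sigma_nd[i], grid$c0_nd[i]),
                       nd0, profiles, cache)
    res[i] <- r$value
  }
  grid$residual <- res
  ib <- which.min(res)
  best <- c(grid$R_Pi[ib], grid$sigma_nd[ib], grid$c0_nd[ib])
  best_val <- res[ib]
  if (refine && is.finite(best_val)) {
    op <- stats::optim(best, function(par) {
      v <- .fit_residual(par, nd0, profiles, cache)$value
      if (!is.finite(v)) 1e6 else v
    }, method = "Nelder-Mead",
    control = list(maxit = 120, reltol = 1e-4,
                   parscale = c(5, 0.05, 0.1)))
    if (op$value < best_val) { best <- op$par; best_val <- op$value }
  }
  fin <- .fit_residual(best, nd0, profiles, cache)
  deg <- grid[is.finite(grid$residual) &
                grid$residual <= degeneracy_tol * best_val, ]
  structure(list(
    R_Pi = best[1], sigma_nd = best[2], c0_nd = best[3],
    f_nd = fin$f_nd, residual = best_val,
    grid = grid, degenerate_set = deg,
    bounds = if (nrow(deg)) list(
      R_Pi = range(deg$R_Pi), sigma_nd = range(deg$sigma_nd),
      c0_nd = range(deg$c0_nd)) else NULL,
    n_profiles = length(profiles),
    heights = vapply(profiles, function(p) attr(p, "L"), numeric(1)),
    cache = cache), class = "invagination_fit")
}

#' Convert a fit to physical parameters
#'
#' Given an assumed turgor pressure, converts the fitted nondimensional
#' parameters to physical ones: `kappa = 2 Pi R_Pi^3`,
#' `sigma = sigma_nd kappa / R_Pi^2`, `C0 = c0_nd / R_Pi`, the force scale
#' `f_Pi`, the initiation force `f0`, per-profile apical forces and the coat
#' radius of curvature `2/C0`; ranges from the degenerate set are
#' propagated.
#'
#' @param fit an [fit_profile] result.
#' @param Pi_assumed turgor pressure \[pN/nm^2\].
#' @param kBT thermal energy \[pN nm\].
#' @return list of physical parameters (units in names).
#' @export
fit_report <- function(fit, Pi_assumed = 1, kBT = 4.1) {
  stopifnot(inherits(fit, "invagination_fit"), Pi_assumed > 0)
  R <- fit$R_Pi
  kappa <- 2 * Pi_assumed * R^3
  f_Pi <- 4 * pi * Pi_assumed * R^2
  C0 <- fit$c0_nd / R
  sigma <- fit$sigma_nd * kappa / R^2
  rng <- function(v, f) if (!is.null(fit$bounds)) f(v) else NULL
  list(
    R_Pi_nm = R,
    kappa_pN_nm = kappa,
    kappa_kBT = kappa / kBT,
    sigma_pN_per_nm = sigma,
    C0_per_nm = C0,
    coat_radius_nm = if (C0 > 0) 2 / C0 else Inf,
    f_Pi_pN = f_Pi,
    f0_pN = 4 * pi * kappa * sqrt(C0^2 + 2 * sigma / kappa),
    f_a_pN = fit$f_nd * f_Pi,
    residual_nm = fit$residual,
    ranges = if (!is.null(fit$bounds)) list(
      R_Pi_nm = fit$bounds$R_Pi,
      kappa_pN_nm = 2 * Pi_assumed * fit$bounds$R_Pi^3,
      kappa_kBT = 2 * Pi_assumed * fit$bounds$R_Pi^3 / kBT,
      C0_per_nm = fit$bounds$c0_nd / rev(fit$bounds$R_Pi),
      sigma_nd = fit$bounds$sigma_nd) else NULL,
    Pi_assumed = Pi_assumed)
}

#' @export
print.invagination_fit <- function(x, ...) {
  cat("Membrane-profile fit (", x$n_profiles, "profile(s) )\n")
  cat(sprintf("  R_Pi = %.2f nm, sigma_nd = %.4f, c0_nd = %.4f\n",
              x$R_Pi, x$sigma_nd, x$c0_nd))
  cat(sprintf("  mean residual = %.3f nm; degenerate set: %d grid points\n",
              x$residual, nrow(x$degenerate_set)))
  if (!is.null(x$bounds))
    cat(sprintf("  degeneracy ranges: R_Pi [%.1f, %.1f] nm, sigma_nd [%.2f, %.2f], c0_nd [%.2f, %.2f]\n",
                x$bounds$R_Pi[1], x$bounds$R_Pi[2],
                x$bounds$sigma_nd[1], x$bounds$sigma_nd[2],
                x$bounds$c0_nd[1], x$bounds$c0_nd[2]))
  invisible(x)
}

#' @export
coef.invagination_fit <- function(object, ...) {
  c(R_Pi = object$R_Pi, sigma_nd = object$sigma_nd, c0_nd = object$c0_nd)
}

#' @export
summary.invagination_fit <- function(object, Pi_assumed = 1, ...) {
  print(object)
  rep <- fit_report(object, Pi_assumed = Pi_assumed)
  cat(sprintf("At Pi = %g pN/nm^2: kappa = %.0f pN nm (%.0f kBT), C0 = %.4f 1/nm\n",
              Pi_assumed, rep$kappa_pN_nm, rep$kappa_kBT, rep$C0_per_nm))
  invisible(object)
}

#' @export
plot.invagination_fit <- function(x, profiles = NULL, ...) {
  g <- x$grid[is.finite(x$grid$residual), ]
  plot(g$R_Pi, g$residual, log = "y", pch = 20, cex = 0.5,
       xlab = "R_Pi [nm]", ylab = "residual [nm]", ...)
  graphics::abline(v = x$R_Pi, col = 2)
  invisible(x)
}
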