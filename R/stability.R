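# Classification of the spontaneous-curvature shape instability: smooth
# force-length curves at low C0, hysteresis (two coexisting branches) above
# C0*, and a no-equilibrium height gap above C0**.

# branch topology -> regime, operating on a traced force_length_curve
.regime_of_curve <- function(cv, Lmax_nd) {
  b <- cv$branches
  ids <- unique(b$branch_id)
  folds <- cv$fold_points
  if (is.null(folds) && length(ids) == 1 &&
      max(b$L_nd) >= Lmax_nd - 0.1 && !any(cv$closure))
    return(list(regime = "smooth", interval = NULL))
  if (length(ids) == 1) {
    foldL <- sort(folds$L_nd)
    if (length(foldL) >= 2)   # connected S-curve
      return(list(regime = "hysteresis",
                  interval = c(foldL[1], foldL[length(foldL)])))
    # single fold, no separate upper branch found
    return(list(regime = "gap", interval = c(max(foldL), NA_real_)))
  }
  b1 <- b[b$branch_id == 1L & b$stable, ]
  b2 <- b[b$branch_id == 2L & b$stable, ]
  if (!nrow(b1) || !nrow(b2))
    return(list(regime = "gap", interval = c(NA_real_, NA_real_)))
  L_A <- max(b1$L_nd)   # upper end of the short (tubular) branch
  L_B <- min(b2$L_nd)   # lower end of the tall (spheroidal) branch
  if (L_B < L_A) list(regime = "hysteresis", interval = c(L_B, L_A))
  else list(regime = "gap", interval = c(L_A, L_B))
}

#' Classify the shape-instability regime
#'
#' Traces the force--length curve over a height range and classifies the
#' branch topology: a single connected branch (`smooth`), two coexisting
#' branches over an overlapping height interval (`hysteresis`), or two
#' branches whose height supports are disjoint, leaving heights with no
#' equilibrium shape (`gap`).
#'
#' @param params a [model_params] with `Gamma = 0` for the isotropic
#'   instability (a `Gamma > 0` input is allowed and typically suppresses
#'   the instability).
#' @param L_range height range \[nm\] scanned (default `0..6 R_Pi`).
#' @param curve optionally, a precomputed [trace_branch] result.
#' @return object of class `stability_report`: regime, the overlap or gap
#'   interval (nm and units of `R_Pi`), tension, thresholds (NA here; see
#'   [find_thresholds]) and the traced curve.
#' @export
classify_regime <- function(params, L_range = NULL, curve = NULL) {
  stopifnot(inherits(params, "model_params"))
  sc <- derived_scales(params)
  if (is.null(L_range)) L_range <- c(0, 6 * sc$R_Pi)
  cv <- if (is.null(curve)) trace_branch(params, L_range = L_range) else curve
  rg <- .regime_of_curve(cv, Lmax_nd = max(L_range) / sc$R_Pi)
  structure(list(
    regime = rg$regime,
    C0_star = NA_real_, C0_starstar = NA_real_,
    interval_nd = rg$interval,
    interval_nm = if (!is.null(rg$interval)) rg$interval * sc$R_Pi else NULL,
    sigma = params$sigma, C0 = params$C0,
    curve = cv, scales = sc), class = "stability_report")
}

#' Locate the instability thresholds C0* and C0**
#'
#' Bisection on the spontaneous curvature with [classify_regime] as the
#' predicate: `C0*` is the onset of branch coexistence (smooth to
#' hysteresis) and `C0**` the onset of the no-equilibrium gap (hysteresis to
#' gap).  Both are reported in units of `1/R_Pi` and `1/nm`.
#'
#' @param params a [model_params] template (its `C0` is ignored).
#' @param sigma membrane tension \[pN/nm\] at which thresholds are computed.
#' @param bracket_star,bracket_starstar initial nondimensional `C0 R_Pi`
#'   brackets; they are expanded if the regime does not change inside.
#' @param tol bisection tolerance in units of `1/R_Pi`.
#' @param L_range scan range \[nm\].
#' @return list with `C0_star_nd`, `C0_starstar_nd` (units 1/R_Pi),
#'   `C0_star`, `C0_starstar` (1/nm), `sigma`, and the bisection history.
#' @export
find_thresholds <- function(params, sigma = params$sigma,
                            bracket_star = c(0.25, 0.55),
                            bracket_starstar = c(0.45, 1.1),
                            tol = 1e-2, L_range = NULL) {
  stopifnot(inherits(params, "model_params"), sigma >= 0)
  params$sigma <- sigma
  sc <- derived_scales(params)
  if (is.null(L_range)) L_range <- c(0, 6 * sc$R_Pi)
  cache <- new.env(parent = emptyenv())
  regime_at <- function(c0nd) {
    key <- sprintf("%.6f", c0nd)
    if (!is.null(cache[[key]])) return(cache[[key]])
    p <- params; p$C0 <- c0nd / sc$R_Pi
    r <- tryCatch(classify_regime(p, L_range = L_range)$regime,
                  error = function(e) "gap")
    cache[[key]] <- r
    r
  }
  bisect <- function(br, pred, what) {
    lo <- br[1]; hi <- br[2]
    # expand bracket if needed
    for (k in 1:4) {
      if (!pred(regime_at(lo))) break
      lo <- lo / 1.5
      if (lo < 0.05) stop("no ", what, " transition found at low C0")
    }
    for (k in 1:4) {
      if (pred(regime_at(hi))) break
      hi <- hi * 1.3
      if (hi > 2) stop("no ", what, " transition found: regime does not ",
                       "change in the searched range")
    }
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (pred(regime_at(mid))) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  }
  C0_star <- bisect(bracket_star, function(r) r != "smooth", "C0*")
  C0_starstar <- bisect(c(max(C0_star, bracket_starstar[1]),
                          bracket_starstar[2]),
                        function(r) r == "gap", "C0**")
  list(C0_star_nd = C0_star, C0_starstar_nd = C0_starstar,
       C0_star = C0_star / sc$R_Pi, C0_starstar = C0_starstar / sc$R_Pi,
       sigma = sigma,
       history = ls(cache))
}

#' Critical spontaneous curvature at fixed height
#'
#' For a fixed invagination height the equilibrium neck closes as the
#' spontaneous curvature increases; `C0+(L)` is the smallest `C0` at which
#' the neck radius falls below `eps` (default `0.01 R_Pi`), beyond which no
#' stable shape with an open neck exists.  Computed by warm-started
#' continuation in `C0` with automatic refinement at the closure point.
#'
#' @param params a [model_params] template (its `C0` is the starting point
#'   if positive, else 0.05/R_Pi).
#' @param L fixed height \[nm\].
#' @param sigma tension \[pN/nm\].
#' @param eps closure threshold in units of `R_Pi`.
#' @param tol tolerance on `C0 R_Pi`.
#' @return list with `C0_plus_nd` (units 1/R_Pi), `C0_plus` (1/nm) and the
#'   neck-radius trace (`c0_nd`, `neck_nd`).
#' @export
critical_curvature_at_length <- function(params, L, sigma = params$sigma,
                                         eps = 1e-2, tol = 1e-2) {
  stopifnot(inherits(params, "model_params"), L > 0)
  params$sigma <- sigma
  sc <- derived_scales(params)
  Lnd <- L / sc$R_Pi
  nd <- nondim_params(params)
  nd$c0 <- if (params$C0 > 0) params$C0 * sc$R_Pi else 0.05
  sol <- .solve_anchor(nd, Lnd)
  if (is.null(sol)) .solver_failure("no equilibrium at the starting C0")
  trace <- list()
  push <- function(c0, s) {
    nk <- if (is.null(s$neck) || is.na(s$neck)) Inf else s$neck
    trace[[length(trace) + 1]] <<- c(c0_nd = c0, neck_nd = nk)
    nk
  }
  nk <- push(nd$c0, sol)
  c0cur <- nd$c0
  step <- 0.04
  upgraded <- !is.null(sol$K) && sol$K > 1
  c0_last_open <- c0cur; c0_closed <- NA_real_
  for (k in 1:200) {
    c0n <- c0cur + step
    ndn <- nd; ndn$c0 <- c0n
    nxt <- .solve_nd(ndn, L = Lnd, guess = sol)
    if (nxt$converged) {
      sol <- nxt; c0cur <- c0n
      nk <- push(c0cur, sol)
      if (nk < eps) { c0_closed <- c0cur; break }
      step <- min(step * 1.3, 0.05)
      # refine once the bracket is tight
    } else {
      if (!upgraded && step < 5e-3) {
        ndc <- nd; ndc$c0 <- c0cur
        up <- .upgrade_to_ms(ndc, sol)
        if (!is.null(up)) { sol <- up; upgraded <- TRUE; next }
      }
      step <- step / 2
      if (step < tol / 4) { c0_closed <- c0cur + 2 * step; break }
    }
    c0_last_open <- c0cur
  }
  tr <- as.data.frame(do.call(rbind, trace))
  C0p <- if (is.na(c0_closed)) NA_real_ else c0_closed
  list(C0_plus_nd = C0p, C0_plus = C0p / sc$R_Pi, trace = tr,
       L = L, sigma = sigma)
}

#' Branch energetics across the hysteresis overlap
#'
#' In the hysteresis regime two equilibrium shapes coexist at equal height.
#' This tabulates the deformation energy and its bending and pressure parts
#' for both branches over the overlap, locates the height where the total
#' energies cross, and checks that the tubular-to-spheroidal transition
#' trades bending energy against pressure energy.
#'
#' @param params a [model_params] in the hysteresis regime.
#' @param L_range scan range \[nm\].
#' @param n_grid number of heights tabulated across the overlap.
#' @param curve optional precomputed [trace_branch] result.
#' @return list with the per-height `table` (energies of both branches, in
#'   pN nm), `L_cross_nm` where total energies cross, and the preferred
#'   branch per height.
#' @export
energy_crossing <- function(params, L_range = NULL, n_grid = 25,
                            curve = NULL) {
  rep0 <- classify_regime(params, L_range = L_range, curve = curve)
  if (rep0$regime != "hysteresis")
    stop("energy_crossing requires the hysteresis regime (got ",
         rep0$regime, ")")
  sc <- rep0$scales
  b <- rep0$curve$branches
  twoPik <- 2 * pi * params$kappa
  iv <- rep0$interval_nd
  Ls <- seq(iv[1] + 1e-3, iv[2] - 1e-3, length.out = n_grid)
  # tubular side: branch 1 stable points; spheroidal side: branch 2 (or the
  # far stable segment of a connected S-curve)
  ids <- unique(b$branch_id)
  if (length(ids) == 2) {
    tub <- b[b$branch_id == 1L & b$stable, ]
    sph <- b[b$branch_id == 2L & b$stable, ]
  } else {
    dl <- c(diff(b$L_nd), 0)
    fold1 <- which.max(b$L_nd)
    tub <- b[seq_len(fold1), ]; tub <- tub[tub$stable, ]
    sph <- b[seq(fold1 + 1, nrow(b)), ]; sph <- sph[sph$stable, ]
  }
  interp <- function(df, col, Ls)
    stats::approx(df$L_nd, df[[col]], Ls, ties = mean)$y
  tab <- data.frame(
    L_nm = Ls * sc$R_Pi,
    E_tub = interp(tub, "E_nd", Ls) * twoPik,
    E_sph = interp(sph, "E_nd", Ls) * twoPik,
    E_bend_tub = interp(tub, "E_bend_nd", Ls) * twoPik,
    E_bend_sph = interp(sph, "E_bend_nd", Ls) * twoPik,
    E_pres_tub = interp(tub, "E_pres_nd", Ls) * twoPik,
    E_pres_sph = interp(sph, "E_pres_nd", Ls) * twoPik)
  tab$preferred <- ifelse(tab$E_sph <= tab$E_tub, "spheroidal", "tubular")
  dE <- tab$E_sph - tab$E_tub
  icross <- which(diff(sign(dE)) != 0)
  L_cross <- if (length(icross)) {
    i <- icross[1]
    with(tab, L_nm[i] + (L_nm[i + 1] - L_nm[i]) *
           abs(dE[i]) / (abs(dE[i]) + abs(dE[i + 1])))
  } else NA_real_
  # at and beyond the crossing the tubular-to-spheroidal switch trades
  # bending energy down against pressure energy up
  post <- !is.na(L_cross) & tab$L_nm >= L_cross
  trade <- any(post) &&
    all(tab$E_bend_sph[post] < tab$E_bend_tub[post], na.rm = TRUE) &&
    all(tab$E_pres_sph[post] > tab$E_pres_tub[post], na.rm = TRUE)
  list(table = tab, L_cross_nm = L_cross, interval_nm = rep0$interval_nm,
       trade_off_at_crossing = trade, regime = rep0$regime)
}

#' BAR-removal scission scenario
#'
#' Starting from an invagination stabilized by anisotropic (BAR-domain)
#' curvature (`Gamma = kappa`, `R0 = R_Pi`) at fixed height, the BAR
#' rigidity is quasi-statically removed (`Gamma -> 0`).  The neck radius is
#' tracked along the continuation; scission is declared when the neck falls
#' below `eps` or no equilibrium remains.
#'
#' @param params a [model_params] with `Gamma > 0` and `R0` set.
#' @param L fixed height \[nm\] (default `6 R_Pi`; the scission scenario
#'   concerns long invaginations).
#' @param eps closure threshold in units of `R_Pi`.
#' @return list with the trace (`Gamma_rel`, `neck_nd`, `f_nd`), the
#'   `Gamma_rel` at scission (or 0 if an open neck survives), and flag
#'   `scission`.
#' @export
scission_test <- function(params, L = NULL, eps = 1e-2) {
  stopifnot(inherits(params, "model_params"))
  if (params$Gamma <= 0) stop("start from a BAR-stabilized state: Gamma > 0")
  sc <- derived_scales(params)
  if (is.null(L)) L <- 6 * sc$R_Pi
  Lnd <- L / sc$R_Pi
  nd <- nondim_params(params)
  sol <- .solve_anchor(nd, Lnd)
  if (is.null(sol))
    .solver_failure("no stabilized equilibrium at the starting Gamma")
  rows <- list()
  push <- function(g, s) {
    nk <- if (is.null(s$neck) || is.na(s$neck)) Inf else s$neck
    rows[[length(rows) + 1]] <<- c(Gamma_rel = g, neck_nd = nk, f_nd = s$ftil)
    nk
  }
  gcur <- nd$Gam
  nk <- push(gcur, sol)
  step <- 0.05
  upgraded <- !is.null(sol$K) && sol$K > 1
  scission <- FALSE; g_scission <- NA_real_
  while (gcur > 0) {
    gnext <- max(gcur - step, 0)
    ndn <- nd; ndn$Gam <- gnext
    ndn$rho0inv <- if (gnext > 0) nd$rho0inv else 0
    nxt <- .solve_nd(ndn, L = Lnd, guess = sol)
    if (nxt$converged) {
      sol <- nxt; gcur <- gnext
      nk <- push(gcur, sol)
      if (nk < eps) { scission <- TRUE; g_scission <- gcur; break }
      step <- min(step * 1.3, 0.08)
    } else {
      if (!upgraded && step < 5e-3) {
        ndc <- nd; ndc$Gam <- gcur
        up <- .upgrade_to_ms(ndc, sol)
        if (!is.null(up)) { sol <- up; upgraded <- TRUE; next }
      }
      step <- step / 2
      if (step < 1e-4) { scission <- TRUE; g_scission <- gcur; break }
    }
  }
  tr <- as.data.frame(do.call(rbind, rows))
  list(trace = tr, scission = scission,
       Gamma_rel_at_scission = g_scission,
       final_neck_nd = tr$neck_nd[nrow(tr)], L = L)
}

#' @export
print.stability_report <- function(x, ...) {
  cat("Shape-instability report (sigma =", x$sigma, "pN/nm, C0 =",
      signif(x$C0, 4), "1/nm)\n")
  cat("  regime:", x$regime, "\n")
  if (!is.null(x$interval_nm) && all(is.finite(x$interval_nm)))
    cat(sprintf("  %s interval: L in [%.2f, %.2f] nm\n",
                if (x$regime == "gap") "gap" else "overlap",
                x$interval_nm[1], x$interval_nm[2]))
  invisible(x)
}

#' Regime diagram over a parameter grid
#'
#' Classifies the shape-instability regime over a grid of spontaneous
#' curvatures and tensions, optionally writing the sweep as CSV with
#' columns `C0_per_RPi,sigma_nd,regime,C0star,C0starstar` (the thresholds
#' are filled in per tension when `thresholds = TRUE`).
#'
#' @param params a [model_params] template.
#' @param c0_values spontaneous curvatures in units of `1/R_Pi`.
#' @param sigma_values reduced tensions `sigma R_Pi^2 / kappa`.
#' @param thresholds also bisect for `C0*`, `C0**` at each tension.
#' @param path optional CSV output path.
#' @return data frame of the sweep (invisibly when written to `path`).
#' @export
regime_diagram <- function(params, c0_values = c(0.2, 0.45, 1),
                           sigma_values = 0, thresholds = FALSE,
                           path = NULL) {
  stopifnot(inherits(params, "model_params"))
  sc <- derived_scales(params)
  rows <- list()
  for (sg in sigma_values) {
    th <- if (thresholds)
      find_thresholds(params, sigma = sg * params$kappa / sc$R_Pi^2)
    else list(C0_star_nd = NA_real_, C0_starstar_nd = NA_real_)
    for (c0 in c0_values) {
      p <- params
      p$sigma <- sg * params$kappa / sc$R_Pi^2
      p$C0 <- c0 / sc$R_Pi
      reg <- tryCatch(classify_regime(p)$regime, error = function(e) NA_character_)
      rows[[length(rows) + 1]] <- data.frame(
        C0_per_RPi = c0, sigma_nd = sg, regime = reg,
        C0star = th$C0_star_nd, C0starstar = th$C0_starstar_nd)
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE)
    return(invisible(out))
  }
  out
}
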