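#' Axisymmetric membrane profile
#'
#' Container for a discretized axisymmetric profile parametrized by arclength
#' from the apex (`s = 0`, `r` = 0, `z = L`) to the contact line
#' (`s = S_total`, `z = 0`, `psi = 0`).  The tangent angle convention is
#' `dr/ds = cos(psi)`, `dz/ds = -sin(psi)`, so a dome tip has
#' `dpsi/ds > 0` and an overhanging neck has `psi > pi/2`.
#'
#' @param s strictly increasing arclength grid \[nm\], starting at (or very
#'   near) 0.
#' @param r radius \[nm\], `>= 0`, 0 at the apex.
#' @param z height above the wall plane \[nm\].
#' @param psi tangent angle \[rad\].
#' @param check validate geometric consistency of the grid (default TRUE).
#' @param tol tolerance for the finite-difference consistency check.
#' @return object of class `shape_profile` (a data frame with columns
#'   `s`, `r`, `z`, `psi`).
#' @export
shape_profile <- function(s, r, z, psi, check = TRUE, tol = 0.05) {
  stopifnot(length(s) == length(r), length(s) == length(z),
            length(s) == length(psi))
  if (any(diff(s) <= 0)) stop("'s' must be strictly increasing")
  if (any(r < -1e-9)) stop("negative radius in profile")
  pr <- data.frame(s = s, r = r, z = z, psi = psi)
  class(pr) <- c("shape_profile", "data.frame")
  if (check && length(s) >= 5) {
    ds <- diff(s)
    i <- seq_len(length(s) - 1)
    mid_psi <- (psi[i] + psi[i + 1]) / 2
    err_r <- abs(diff(r) / ds - cos(mid_psi))
    err_z <- abs(diff(z) / ds + sin(mid_psi))
    # worst-case relative to grid scale; interior only (apex row is series)
    if (stats::median(err_r) > tol || stats::median(err_z) > tol)
      warning("profile fails geometric consistency: |dr/ds - cos psi| or ",
              "|dz/ds + sin psi| above tolerance")
  }
  pr
}

# curvatures on the grid; azimuthal curvature sin(psi)/r regularized at the
# apex by its limit dpsi/ds
profile_curvatures <- function(pr) {
  n <- nrow(pr)
  u <- numeric(n)  # meridional dpsi/ds by central differences
  s <- pr$s; psi <- pr$psi
  u[2:(n - 1)] <- (psi[3:n] - psi[1:(n - 2)]) / (s[3:n] - s[1:(n - 2)])
  u[1] <- (psi[2] - psi[1]) / (s[2] - s[1])
  u[n] <- (psi[n] - psi[n - 1]) / (s[n] - s[n - 1])
  az <- ifelse(pr$r > 1e-9, sin(psi) / pr$r, u)
  list(meridional = u, azimuthal = az)
}

#' Energy breakdown of a membrane profile
#'
#' Evaluates every term of the invagination energy on a discretized profile by
#' composite-trapezoid quadrature over the detached membrane surface:
#' bending `int kappa/2 (C - C0)^2 dS` with `C = dpsi/ds + sin(psi)/r`,
#' tension `sigma S`, pressure `Pi V`, the anisotropic BAR term
#' `int Gamma/2 (sin(psi)/r - 1/R0)^2 dS` (with the flat-coated-state
#' reference `E_bar_ref = -Gamma/(2 R0^2) pi r_c^2` for a uniformly
#' BAR-coated membrane), and the work term `-f_a L`.
#'
#' All surface terms are integrals over the detached membrane only, so the
#' flat attached membrane carries zero energy; `F_total` is exactly the sum
#' of all stored components including the work term, and
#' `E_deform = F_total + f_a L` vanishes as `L -> 0`.
#'
#' @param profile a [shape_profile].
#' @param params a [model_params].
#' @param f_a apical force \[pN\] entering the work term (default 0).
#' @param min_nodes minimum number of grid nodes accepted (resolution guard).
#' @return list of class `energy_breakdown` with components `E_bend`,
#'   `E_tension`, `E_pressure`, `E_bar`, `work`, `F_total`, `E_deform`,
#'   all in pN nm.
#' @export
evaluate_energy <- function(profile, params, f_a = 0, min_nodes = 50) {
  stopifnot(inherits(profile, "shape_profile"), inherits(params, "model_params"))
  n <- nrow(profile)
  if (n < min_nodes)
    stop("profile grid too coarse: need at least ", min_nodes, " nodes")
  if (any(profile$r < -1e-9)) stop("invalid profile: negative radius")
  cv <- profile_curvatures(profile)
  C <- cv$meridional + cv$azimuthal
  r <- profile$r; s <- profile$s
  trapz <- function(y) sum(diff(s) * (y[-1] + y[-n]) / 2)
  E_bend <- trapz(params$kappa / 2 * (C - params$C0)^2 * 2 * pi * r)
  S <- trapz(2 * pi * r)
  E_tension <- params$sigma * S
  V <- trapz(pi * r^2 * sin(profile$psi))
  E_pressure <- params$Pi * V
  E_bar <- if (params$Gamma > 0)
    trapz(params$Gamma / 2 * (cv$azimuthal - 1 / params$R0)^2 * 2 * pi * r)
  else 0
  E_bar_ref <- if (params$Gamma > 0)
    -params$Gamma / (2 * params$R0^2) * pi * r[n]^2 else 0
  L <- profile$z[1]
  work <- -f_a * L
  F_total <- E_bend + E_tension + E_pressure + E_bar + E_bar_ref + work
  out <- list(E_bend = E_bend, E_tension = E_tension, E_pressure = E_pressure,
              E_bar = E_bar, E_bar_ref = E_bar_ref, work = work,
              F_total = F_total, E_deform = F_total + f_a * L)
  class(out) <- "energy_breakdown"
  out
}

#' Geometric observables of a profile
#'
#' @param profile a [shape_profile].
#' @return list with invagination height `L` \[nm\], enclosed volume `V`
#'   \[nm^3\], detached membrane area `S` \[nm^2\], projected detached wall
#'   area `S0 = pi r_c^2` \[nm^2\], `neck_radius` \[nm\] (smallest interior
#'   local minimum of `r(s)`, `NA` when the profile has no neck) and
#'   `tip_radius` \[nm\] (inverse apex curvature).
#' @export
geometric_observables <- function(profile) {
  stopifnot(inherits(profile, "shape_profile"))
  n <- nrow(profile)
  r <- profile$r; s <- profile$s
  trapz <- function(y) sum(diff(s) * (y[-1] + y[-n]) / 2)
  V <- trapz(pi * r^2 * sin(profile$psi))
  S <- trapz(2 * pi * r)
  cv <- profile_curvatures(profile)
  idx <- which(diff(sign(diff(r))) > 0) + 1   # interior local minima of r
  idx <- idx[idx > 2 & idx < n]
  neck <- if (length(idx)) min(r[idx]) else NA_real_
  list(L = profile$z[1], V = V, S = S, S0 = pi * r[n]^2,
       neck_radius = neck, tip_radius = 1 / cv$meridional[1])
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat("Energy breakdown [pN nm]\n")
  for (nm in c("E_bend", "E_tension", "E_pressure", "E_bar", "E_bar_ref",
               "work", "F_total", "E_deform"))
    cat(sprintf("  %-10s %12.4f\n", nm, x[[nm]]))
  invisible(x)
}
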