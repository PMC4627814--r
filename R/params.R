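#' Physical parameters of the pressurized-membrane model
#'
#' Bundles the continuum parameters of an endocytic invagination in a walled
#' cell: the membrane (plus coat) bending rigidity, membrane tension, turgor
#' pressure, isotropic spontaneous curvature induced by coat proteins, and the
#' anisotropic (BAR-domain) curvature module.  Units are fixed package-wide:
#' nm for lengths, pN for forces, pN nm for energies, pN/nm for tension and
#' pN/nm^2 for pressure (1 pN/nm^2 = 1 MPa).
#'
#' @param kappa bending rigidity of the coated membrane \[pN nm\]
#'   (40 kBT = 164 pN nm is a bare bilayer; a coated membrane is much stiffer).
#' @param sigma membrane tension \[pN/nm\]; 1e-3 N/m = 1 pN/nm.
#' @param Pi turgor pressure \[pN/nm^2\].
#' @param C0 isotropic spontaneous (total) curvature \[1/nm\]; positive values
#'   favour the tip-like bulge.
#' @param Gamma rigidity of the BAR-coated membrane \[pN nm\]; 0 disables the
#'   anisotropic term.
#' @param R0 preferred azimuthal radius of curvature of the BAR coat \[nm\];
#'   required when `Gamma > 0`.
#' @param kBT thermal energy constant \[pN nm\], fixed at 4.1 by convention.
#' @return An object of class `model_params`.
#' @examples
#' p <- model_params(kappa = 160, sigma = 0, Pi = 1, C0 = 0.02)
#' derived_scales(p)
#' @export
model_params <- function(kappa, sigma = 0, Pi = 1, C0 = 0, Gamma = 0,
                         R0 = NA_real_, kBT = 4.1) {
  stopifnot(is.numeric(kappa), is.numeric(sigma), is.numeric(Pi),
            is.numeric(C0), is.numeric(Gamma))
  if (!is.finite(kappa) || kappa <= 0) stop("'kappa' must be positive")
  if (!is.finite(Pi) || Pi <= 0) stop("'Pi' must be positive")
  if (sigma < 0) stop("'sigma' must be >= 0")
  if (Gamma < 0) stop("'Gamma' must be >= 0")
  if (Gamma > 0 && (!is.finite(R0) || R0 <= 0))
    stop("'R0' must be positive when 'Gamma' > 0")
  p <- list(kappa = kappa, sigma = sigma, Pi = Pi, C0 = C0,
            Gamma = Gamma, R0 = R0, kBT = kBT)
  class(p) <- "model_params"
  p
}

#' Derived length and force scales
#'
#' The pressure--rigidity length `R_Pi = (kappa/2 Pi)^(1/3)` sets the natural
#' width of a pressure-dominated invagination; the tension--rigidity length
#' `lambda = sqrt(kappa/2 sigma)` the width of a tension-dominated one; and
#' `f_Pi = 4 pi Pi R_Pi^2 = 2 pi kappa / R_Pi` the natural force scale.
#'
#' @param params a [model_params] object.
#' @return list with `R_Pi` \[nm\], `lambda` \[nm\] (`Inf` when `sigma = 0`)
#'   and `f_Pi` \[pN\].
#' @export
derived_scales <- function(params) {
  stopifnot(inherits(params, "model_params"))
  R_Pi <- (params$kappa / (2 * params$Pi))^(1 / 3)
  lambda <- if (params$sigma > 0) sqrt(params$kappa / (2 * params$sigma)) else Inf
  f_Pi <- 4 * pi * params$Pi * R_Pi^2
  list(R_Pi = R_Pi, lambda = lambda, f_Pi = f_Pi)
}

# Nondimensional parameter block used by the solver: curvatures in 1/R_Pi,
# tension as sigma R_Pi^2 / kappa, rigidities relative to kappa.
nondim_params <- function(params, het = NULL) {
  sc <- derived_scales(params)
  nd <- list(
    c0 = params$C0 * sc$R_Pi,
    sig = params$sigma * sc$R_Pi^2 / params$kappa,
    Gam = params$Gamma / params$kappa,
    rho0inv = if (params$Gamma > 0) sc$R_Pi / params$R0 else 0,
    het = FALSE, kmin = 1, atip = 1, wa = 1
  )
  if (!is.null(het)) {
    nd$het <- TRUE
    nd$kmin <- het$kappa_min / het$kappa_tip
    nd$atip <- het$A_tip / (2 * pi * sc$R_Pi^2)
    nd$wa <- het$w / sc$R_Pi
  }
  nd
}

#' Analytic initiation force
#'
#' Apical force required at the onset of invagination (the `L -> 0` limit of
#' the force--length relation): `f0 = 4 pi kappa sqrt(C0^2 + 2 sigma/kappa)`,
#' which reduces to `f0 = 4 pi kappa C0` for a tension-free membrane.  The
#' general form is validated numerically against the boundary-value solver in
#' the package tests.
#'
#' @param params a [model_params] object.
#' @return initiation force \[pN\].
#' @export
initiation_force <- function(params) {
  stopifnot(inherits(params, "model_params"))
  4 * pi * params$kappa *
    sqrt(params$C0^2 + 2 * params$sigma / params$kappa)
}

#' Asymptotic tube (plateau) limit
#'
#' Radius and force of the infinite-tube asymptote reached by long
#' invaginations, obtained by minimizing the per-unit-length energy
#' `e(R) = pi kappa (1/R - C0)^2 R + 2 pi sigma R + Pi pi R^2` over the tube
#' radius.  The plateau force equals the minimal per-length energy.
#'
#' @param params a [model_params] object with `Gamma = 0`.
#' @return list with `radius` \[nm\], `force` \[pN\] and their nondimensional
#'   counterparts `radius_nd` (units `R_Pi`) and `force_nd` (units `f_Pi`).
#' @export
tube_limit <- function(params) {
  stopifnot(inherits(params, "model_params"))
  if (params$Gamma != 0)
    stop("tube_limit is defined for the isotropic model (Gamma = 0)")
  nd <- nondim_params(params)
  sc <- derived_scales(params)
  elen <- function(rho) {
    0.5 * rho * (1 / rho - nd$c0)^2 + nd$sig * rho + 0.25 * rho^2
  }
  op <- stats::optimize(elen, c(1e-3, 50), tol = 1e-12)
  if (op$minimum < 2e-3 || op$minimum > 49)
    stop("no interior tube radius: degenerate parameters")
  list(radius_nd = op$minimum, force_nd = op$objective,
       radius = op$minimum * sc$R_Pi, force = op$objective * sc$f_Pi)
}

#' Quasi-static relaxation timescale
#'
#' Time for the membrane to relax over a distance `L` against membrane drag
#' `eta_m` under force `f`; orders of magnitude below the seconds-long
#' duration of an endocytic event, which justifies solving for static
#' equilibria at every stage.
#'
#' @param L distance \[nm\].
#' @param eta_m membrane drag coefficient \[kg/s\].
#' @param f driving force \[pN\].
#' @return relaxation time \[s\].
#' @export
quasistatic_timescale <- function(L, eta_m, f) {
  stopifnot(L >= 0, eta_m > 0)
  if (f <= 0) stop("'f' must be positive")
  # L [nm] * 1e-9 * eta [kg/s] / (f [pN] * 1e-12) seconds
  L * eta_m / f * 1e3
}

#' Coat-adhesion pulling force
#'
#' Maximal pulling force that coat-protein adhesion of energy density `omega`
#' can exert on an invagination of radius `R`: `pi * omega * R`.  For
#' realistic adhesion energies this is tens of pN, far below the
#' pressure-scale forces, so adhesion alone cannot drive invagination in a
#' turgid cell.
#'
#' @param omega adhesion energy density \[pN/nm\] (1e-3 N/m = 1 pN/nm).
#' @param R invagination radius \[nm\].
#' @return force \[pN\].
#' @export
coat_adhesion_force <- function(omega, R) {
  stopifnot(omega >= 0, R > 0)
  pi * omega * R
}

#' @export
print.model_params <- function(x, ...) {
  sc <- derived_scales(x)
  cat("Membrane model parameters\n")
  cat(sprintf("  kappa  = %g pN nm (%.0f kBT)\n", x$kappa, x$kappa / x$kBT))
  cat(sprintf("  sigma  = %g pN/nm\n", x$sigma))
  cat(sprintf("  Pi     = %g pN/nm^2\n", x$Pi))
  cat(sprintf("  C0     = %g 1/nm (C0 R_Pi = %.3f)\n", x$C0, x$C0 * sc$R_Pi))
  if (x$Gamma > 0)
    cat(sprintf("  Gamma  = %g pN nm, R0 = %g nm\n", x$Gamma, x$R0))
  cat(sprintf("Scales: R_Pi = %.3f nm, lambda = %.3f nm, f_Pi = %.1f pN\n",
              sc$R_Pi, sc$lambda, sc$f_Pi))
  invisible(x)
}
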