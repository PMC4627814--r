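#' Heterogeneous rigidity profile
#'
#' Describes a coated membrane whose bending rigidity is `kappa_tip` over a
#' stiff apical cap of membrane area `A_tip` (clathrin-coated tip) and decays
#' smoothly to `kappa_min` (bare base) over a transition of arclength width
#' `w`.  Inside the shape equations the rigidity is a smooth function of
#' accumulated membrane area from the apex,
#' `kappa(A) = kappa_min + (kappa_tip - kappa_min) (1 - tanh((A - A_tip)/W_A))/2`
#' with the area width `W_A = 2 pi R_Pi w`.
#'
#' @param kappa_tip rigidity of the apical cap \[pN nm\].
#' @param kappa_min rigidity of the base \[pN nm\], `<= kappa_tip`.
#' @param A_tip membrane area of the stiff region \[nm^2\].
#' @param w transition width in arclength \[nm\].
#' @return object of class `rigidity_profile`.
#' @export
rigidity_profile <- function(kappa_tip, kappa_min, A_tip, w) {
  stopifnot(kappa_tip > 0, kappa_min > 0, A_tip > 0, w > 0)
  if (kappa_min > kappa_tip)
    stop("'kappa_min' must not exceed 'kappa_tip'")
  structure(list(kappa_tip = kappa_tip, kappa_min = kappa_min,
                 A_tip = A_tip, w = w), class = "rigidity_profile")
}

#' Solve the equilibrium shape with heterogeneous rigidity
#'
#' As [solve_shape] but with a spatially varying bending rigidity described
#' by a [rigidity_profile].  The pressure--rigidity scale `R_Pi` and force
#' scale `f_Pi` are defined from `kappa_tip`.  With
#' `kappa_min == kappa_tip` the computation reduces to the homogeneous
#' solver on an identical code path.  When the base is too soft no
#' equilibrium exists for a range of heights (rigidity-driven shape
#' instability) and a no-equilibrium condition is signalled.
#'
#' @param params a [model_params]; its `kappa` is overridden by
#'   `rigidity$kappa_tip`.
#' @param rigidity a [rigidity_profile].
#' @param L target height \[nm\].
#' @param f_a imposed apical force \[pN\].
#' @param guess optional warm start (`$nondim` of a nearby solution).
#' @param nper profile grid density.
#' @return a `shape_solution` (see [solve_shape]); `$rigidity` carries the
#'   rigidity profile.
#' @export
solve_heterogeneous <- function(params, rigidity, L = NULL, f_a = NULL,
                                guess = NULL, nper = 300) {
  stopifnot(inherits(params, "model_params"),
            inherits(rigidity, "rigidity_profile"))
  if (is.null(L) == is.null(f_a)) stop("give exactly one of 'L' or 'f_a'")
  params$kappa <- rigidity$kappa_tip
  if (rigidity$kappa_min == rigidity$kappa_tip)
    return(solve_shape(params, L = L, f_a = f_a, guess = guess, nper = nper))
  nd <- nondim_params(params, het = rigidity)
  sc <- derived_scales(params)
  if (!is.null(L)) {
    Lnd <- L / sc$R_Pi
    sol <- .solve_nd(nd, L = Lnd, guess = guess)
    if (!sol$converged && is.null(guess))
      sol <- .solve_het_homotopy(nd, params, rigidity, Lnd)
    if (!sol$converged)
      .no_equilibrium(sprintf(
        "no heterogeneous equilibrium at L = %.3g nm with kappa_min/kappa_tip = %.3g (rigidity instability)",
        L, rigidity$kappa_min / rigidity$kappa_tip), sol)
  } else {
    sol <- .solve_nd(nd, ftil = f_a / sc$f_Pi, guess = guess)
    if (!sol$converged)
      .solver_failure("heterogeneous shape solver failed to converge", sol)
  }
  .make_solution(nd, params, sol, nper = nper, het_spec = rigidity)
}

# homotopy in kappa_min from the homogeneous problem down to the target
.solve_het_homotopy <- function(nd, params, rigidity, Lnd, max_steps = 60) {
  nd_hom <- nd; nd_hom$het <- FALSE
  base <- .solve_anchor(nd_hom, Lnd)
  if (is.null(base)) return(list(converged = FALSE))
  # re-represent with the heterogeneous layout (mu0 = 0 appended)
  kt <- 1; ktarget <- nd$kmin
  kcur <- kt
  sol <- base
  sol$K <- if (is.null(base$K)) 1L else base$K
  sol$theta <- append(base$theta, 0, after = 3)   # insert mu0 after Sigma
  step <- -min(0.1, kt - ktarget)
  for (k in seq_len(max_steps)) {
    knext <- max(kcur + step, ktarget)
    ndn <- nd; ndn$kmin <- knext
    nxt <- .solve_nd(ndn, L = Lnd, guess = sol)
    if (nxt$converged) {
      sol <- nxt; kcur <- knext
      if (abs(kcur - ktarget) < 1e-12) return(sol)
      step <- -min(abs(step) * 1.5, 0.15)
    } else {
      step <- step / 2
      if (abs(step) < 1e-3) return(list(converged = FALSE, k_last = kcur))
    }
  }
  list(converged = FALSE, k_last = kcur)
}

#' Critical rigidity ratio of the base
#'
#' Smallest ratio `kappa_min/kappa_tip` for which equilibria exist over the
#' whole height range: below it the soft base destabilizes the invagination
#' even without spontaneous curvature.  Located by bisection on the ratio,
#' using fold-free continuation over `L_range` as the stability predicate.
#'
#' @param params a [model_params] (typically `C0 = 0`).
#' @param A_tip stiff-cap membrane area \[nm^2\].
#' @param w transition width \[nm\].
#' @param L_range height range \[nm\] over which equilibria are required.
#' @param tol bisection tolerance on the ratio.
#' @return list with `ratio_critical` and the bisection history.
#' @export
critical_rigidity_ratio <- function(params, A_tip, w, L_range = NULL,
                                    tol = 0.02) {
  stopifnot(inherits(params, "model_params"))
  sc <- derived_scales(params)
  if (is.null(L_range)) L_range <- c(0, 5 * sc$R_Pi)
  stable_at <- function(ratio) {
    rg <- rigidity_profile(params$kappa, ratio * params$kappa, A_tip, w)
    cv <- tryCatch(trace_branch(params, L_range = L_range, rigidity = rg),
                   error = function(e) NULL)
    if (is.null(cv)) return(FALSE)
    b <- cv$branches
    no_fold <- is.null(cv$fold_points)
    covers <- max(b$L_nm) >= max(L_range) * 0.98
    no_fold && covers && !any(cv$closure)
  }
  lo <- 0.05; hi <- 1
  hist <- list()
  if (!stable_at(hi)) stop("homogeneous configuration itself is unstable")
  while (lo > 0.012 && stable_at(lo)) lo <- lo / 2
  for (k in 1:30) {
    if (hi - lo < tol) break
    mid <- (lo + hi) / 2
    ok <- stable_at(mid)
    hist[[length(hist) + 1]] <- c(ratio = mid, stable = ok)
    if (ok) hi <- mid else lo <- mid
  }
  list(ratio_critical = (lo + hi) / 2,
       bracket = c(lo, hi),
       history = do.call(rbind, hist))
}

#' @export
print.rigidity_profile <- function(x, ...) {
  cat(sprintf(
    "Rigidity profile: kappa_tip = %g, kappa_min = %g pN nm (ratio %.3f)\n",
    x$kappa_tip, x$kappa_min, x$kappa_min / x$kappa_tip))
  cat(sprintf("  stiff cap area %g nm^2, transition width %g nm\n",
              x$A_tip, x$w))
  invisible(x)
}
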