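# Synthetic pseudo-tomography contour generator: produces 2D traced-contour
# data with the statistical structure the fitting pipeline assumes
# (tracing noise, axis offset, low-frequency skew), from forward-model
# equilibrium shapes.

#' Specification for synthetic contour generation
#'
#' Defaults emulate the geometry of endocytic invaginations in yeast
#' electron tomograms: heights up to ~120 nm, tip radius ~12 nm at the
#' fitted parameter scale (`R_Pi = 20` nm, `c0_nd = 0.4`), point spacing
#' 2--5 nm along the contour, ~1 nm Gaussian tracing noise and mild
#' left-right asymmetry that rectification must remove.
#'
#' @param params a [model_params]; the default uses `R_Pi = 20` nm
#'   (`kappa = 2 Pi R_Pi^3` at `Pi = 1` pN/nm^2), `C0 = 0.4/R_Pi`,
#'   `sigma = 0`.
#' @param heights contour heights \[nm\].
#' @param noise_sd isotropic Gaussian point displacement SD \[nm\].
#' @param axis_offset horizontal offset of the traced axis \[nm\].
#' @param skew_amp amplitude of a single-mode sinusoidal skew field \[nm\]
#'   (emulates tilt/tracing artifacts).
#' @param spacing point spacing along the contour \[nm\].
#' @param seed integer seed; all outputs record it.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(params = NULL,
                           heights = c(0.5, 1.5, 3, 5) * 20,
                           noise_sd = 1, axis_offset = 2, skew_amp = 1.5,
                           spacing = 3, seed = 1L) {
  if (is.null(params)) {
    R_Pi <- 20
    params <- model_params(kappa = 2 * 1 * R_Pi^3, sigma = 0, Pi = 1,
                           C0 = 0.4 / R_Pi)
  }
  stopifnot(inherits(params, "model_params"), noise_sd >= 0, spacing > 0)
  structure(list(params = params, heights = heights, noise_sd = noise_sd,
                 axis_offset = axis_offset, skew_amp = skew_amp,
                 spacing = spacing, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate one synthetic contour
#'
#' Solves the forward model at height `L`, mirrors the axisymmetric profile
#' into a 2D contour (left base to apex to right base), resamples it at the
#' requested spacing, then applies the axis offset, the smooth skew field
#' and i.i.d. Gaussian point noise.  Deterministic given `spec$seed` and
#' `L`.
#'
#' @param spec a [synthetic_spec].
#' @param L contour height \[nm\] (must be solvable for `spec$params`).
#' @param solution optional precomputed `shape_solution` at `L`.
#' @return a [contour2d]; attribute `truth` carries the generating
#'   parameters and the solution observables.
#' @export
generate_contour <- function(spec, L, solution = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  sol <- if (is.null(solution)) solve_shape(spec$params, L = L) else solution
  pr <- sol$profile
  # resample profile at constant arclength spacing
  smax <- max(pr$s)
  ns <- max(ceiling(smax / spec$spacing), 8)
  sg <- seq(0, smax, length.out = ns + 1)
  r <- stats::approx(pr$s, pr$r, sg, rule = 2)$y
  z <- stats::approx(pr$s, pr$z, sg, rule = 2)$y
  r[1] <- 0
  # mirrored contour: left side base->apex, right side apex->base
  xs <- c(-rev(r), r[-1])
  ys <- c(rev(z), z[-1])
  rng <- .local_rng(spec$seed + 1009L * as.integer(round(10 * L)))
  on.exit(rng())
  skew <- spec$axis_offset +
    spec$skew_amp * sin(pi * ys / max(ys))
  xs <- xs + skew
  if (spec$noise_sd > 0) {
    xs <- xs + stats::rnorm(length(xs), 0, spec$noise_sd)
    ys <- ys + stats::rnorm(length(ys), 0, spec$noise_sd)
  }
  ct <- contour2d(xs, ys, seed = spec$seed)
  attr(ct, "truth") <- list(
    R_Pi = derived_scales(spec$params)$R_Pi,
    sigma_nd = nondim_params(spec$params)$sig,
    c0_nd = nondim_params(spec$params)$c0,
    L = L, f_a = sol$f_a, tip_radius = sol$observables$tip_radius,
    neck_radius = sol$observables$neck_radius,
    noise_sd = spec$noise_sd, seed = spec$seed)
  ct
}

# swap in a deterministic RNG state; returns a restore function
.local_rng <- function(seed) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }
}

#' Generate a benchmark suite of contours with ground truth
#'
#' Writes a ladder of contours at the spec heights, plus one necked profile
#' (hysteresis-regime spheroid) and one near-closure profile (spontaneous
#' curvature close to the critical value), together with a `truth.json`
#' recording the generating parameters of every file.
#'
#' @param spec a [synthetic_spec].
#' @param dir output directory (created if missing); `NULL` returns the
#'   contours without writing.
#' @return (invisibly) list with `contours` (named list of [contour2d]) and
#'   `truth` (list as written to `truth.json`).
#' @export
make_benchmark_suite <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  sc <- derived_scales(spec$params)
  contours <- list()
  truth <- list()
  for (L in spec$heights) {
    nm <- sprintf("contour_L%03d", round(L))
    ct <- generate_contour(spec, L)
    contours[[nm]] <- ct
    truth[[nm]] <- attr(ct, "truth")
  }
  # necked profile: hysteresis-regime spheroid
  p_neck <- spec$params
  p_neck$C0 <- 0.45 / sc$R_Pi
  spec_neck <- spec; spec_neck$params <- p_neck
  ct <- generate_contour(spec_neck, 4 * sc$R_Pi)
  contours$contour_necked <- ct
  truth$contour_necked <- attr(ct, "truth")
  # near-closure profile: C0 close to the critical curvature at this height
  p_close <- spec$params
  p_close$C0 <- 0.7 / sc$R_Pi
  spec_close <- spec; spec_close$params <- p_close
  ct <- generate_contour(spec_close, 2.8 * sc$R_Pi)
  contours$contour_nearclosure <- ct
  truth$contour_nearclosure <- attr(ct, "truth")
  truth$spec <- list(noise_sd = spec$noise_sd,
                     axis_offset = spec$axis_offset,
                     skew_amp = spec$skew_amp, spacing = spec$spacing,
                     seed = spec$seed,
                     package_version = as.character(utils::packageVersion("endomech")))
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (nm in names(contours))
      write_contour_csv(contours[[nm]], file.path(dir, paste0(nm, ".csv")))
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(contours = contours, truth = truth))
}
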