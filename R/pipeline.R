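# Configuration-driven pipeline entry points.  Each takes a config (a named
# list, or a path to a JSON file with the same structure), runs one stage of
# the analysis and writes its outputs together with the resolved config, the
# package version and the seed, so a run can be reproduced from its own
# output directory.

.load_config <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  if (!is.list(config)) stop("config must be a list or a JSON file path")
  config
}

.config_params <- function(config) {
  pb <- config$model
  if (is.null(pb)) stop("config validation: missing 'model' block")
  need <- c("kappa_pN_nm", "Pi_pN_per_nm2")
  miss <- setdiff(need, names(pb))
  if (length(miss)) stop("config validation: missing model keys: ",
                         paste(miss, collapse = ", "))
  model_params(
    kappa = pb$kappa_pN_nm,
    sigma = if (!is.null(pb$sigma_pN_per_nm)) pb$sigma_pN_per_nm else 0,
    Pi = pb$Pi_pN_per_nm2,
    C0 = if (!is.null(pb$C0_per_nm)) pb$C0_per_nm else 0,
    Gamma = if (!is.null(pb$Gamma_pN_nm)) pb$Gamma_pN_nm else 0,
    R0 = if (!is.null(pb$R0_nm)) pb$R0_nm else NA_real_)
}

.emit_config <- function(config, out_dir) {
  config$package_version <- as.character(utils::packageVersion("endomech"))
  jsonlite::write_json(config, file.path(out_dir, "config_resolved.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

.out_dir <- function(config) {
  od <- if (!is.null(config$out_dir)) config$out_dir else "."
  if (!dir.exists(od)) dir.create(od, recursive = TRUE)
  od
}

#' Pipeline stages driven by a configuration
#'
#' Thin orchestration wrappers around the package functions, reading a
#' config list (or JSON path) and writing results plus the resolved config
#' to `config$out_dir`.  `run_solve` solves one equilibrium shape
#' (`config$target$L_nm` or `config$target$fa_pN`); `run_sweep` traces the
#' force--length curve and classifies the regime (optionally locating
#' thresholds when `config$thresholds = TRUE`); `run_fit` rectifies and fits
#' contour CSV files listed in `config$contours`; `run_simulate` writes a
#' synthetic benchmark suite.
#'
#' Solver failures raise conditions of class `endomech_solver_failure` or
#' `endomech_no_equilibrium`; config problems raise ordinary errors.
#'
#' @param config named list or path to a JSON config file.
#' @return the primary result object of the stage, invisibly; files are
#'   written to `config$out_dir`.
#' @export
run_solve <- function(config) {
  config <- .load_config(config)
  params <- .config_params(config)
  if (is.null(config$target) ||
      (is.null(config$target$L_nm) && is.null(config$target$fa_pN)))
    stop("config validation: 'target' needs 'L_nm' or 'fa_pN'")
  od <- .out_dir(config)
  sol <- solve_shape(params, L = config$target$L_nm,
                     f_a = config$target$fa_pN)
  write_solution(sol, file.path(od, "solution"))
  .emit_config(config, od)
  invisible(sol)
}

#' @rdname run_solve
#' @export
run_sweep <- function(config) {
  config <- .load_config(config)
  params <- .config_params(config)
  od <- .out_dir(config)
  L_range <- if (!is.null(config$L_range_nm)) unlist(config$L_range_nm)
             else NULL
  cv <- trace_branch(params, L_range = L_range)
  write_curve_csv(cv, file.path(od, "force_length.csv"))
  rep <- classify_regime(params, L_range = L_range, curve = cv)
  if (isTRUE(config$thresholds)) {
    th <- find_thresholds(params)
    rep$C0_star <- th$C0_star
    rep$C0_starstar <- th$C0_starstar
  }
  write_stability_json(rep, file.path(od, "stability.json"))
  .emit_config(config, od)
  invisible(list(curve = cv, report = rep))
}

#' @rdname run_solve
#' @export
run_fit <- function(config) {
  config <- .load_config(config)
  od <- .out_dir(config)
  files <- unlist(config$contours)
  if (!length(files)) stop("config validation: empty contour list")
  profs <- lapply(files, function(f) rectify_contour(read_contour_csv(f)))
  fo <- config$fit_options
  args <- list(profiles = profs)
  if (!is.null(fo$grid_R_Pi)) args$grid_R_Pi <- unlist(fo$grid_R_Pi)
  if (!is.null(fo$grid_sigma)) args$grid_sigma <- unlist(fo$grid_sigma)
  if (!is.null(fo$grid_c0)) args$grid_c0 <- unlist(fo$grid_c0)
  if (!is.null(fo$refine)) args$refine <- fo$refine
  fit <- do.call(fit_profile, args)
  Pi_assumed <- if (!is.null(config$Pi_assumed)) config$Pi_assumed else 1
  rep <- fit_report(fit, Pi_assumed = Pi_assumed)
  jsonlite::write_json(list(
    best = list(R_Pi_nm = fit$R_Pi, sigma_nd = fit$sigma_nd,
                c0_nd = fit$c0_nd, residual_nm = fit$residual),
    physical = rep[c("kappa_pN_nm", "kappa_kBT", "sigma_pN_per_nm",
                     "C0_per_nm", "coat_radius_nm", "f_Pi_pN", "f0_pN",
                     "f_a_pN")],
    degenerate_set = fit$degenerate_set,
    heights_nm = fit$heights,
    seed = config$seed,
    package_version = as.character(utils::packageVersion("endomech"))),
    file.path(od, "fit.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  .emit_config(config, od)
  invisible(fit)
}

#' @rdname run_solve
#' @export
run_simulate <- function(config) {
  config <- .load_config(config)
  od <- .out_dir(config)
  params <- if (!is.null(config$model)) .config_params(config) else NULL
  sb <- config$synthetic
  spec <- synthetic_spec(
    params = params,
    heights = if (!is.null(sb$heights_nm)) unlist(sb$heights_nm)
              else c(0.5, 1.5, 3, 5) * 20,
    noise_sd = if (!is.null(sb$noise_sd)) sb$noise_sd else 1,
    axis_offset = if (!is.null(sb$axis_offset)) sb$axis_offset else 2,
    skew_amp = if (!is.null(sb$skew_amp)) sb$skew_amp else 1.5,
    spacing = if (!is.null(sb$spacing)) sb$spacing else 3,
    seed = if (!is.null(config$seed)) config$seed else 1L)
  suite <- make_benchmark_suite(spec, dir = od)
  .emit_config(config, od)
  invisible(suite)
}
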