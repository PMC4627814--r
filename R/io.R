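# CSV/JSON plumbing.  All file formats are plain text: contour CSV
# (x_nm,y_nm), axisymmetric profile CSV (s_nm,r_nm,z_nm,psi_rad), rectified
# profile CSV (z_nm,r_nm), force-length curve CSV
# (branch_id,L_nm,fa_pN,E_pNnm,neck_nm,stable), parameter JSON with unit-
# suffixed keys.

#' Read and write model parameters as JSON
#'
#' Keys carry units: `kappa_pN_nm`, `sigma_pN_per_nm`, `Pi_pN_per_nm2`,
#' `C0_per_nm`, `Gamma_pN_nm`, `R0_nm`.
#'
#' @param params a [model_params].
#' @param path file path.
#' @return `read_params_json` returns a [model_params].
#' @export
write_params_json <- function(params, path) {
  stopifnot(inherits(params, "model_params"))
  jsonlite::write_json(list(
    kappa_pN_nm = params$kappa, sigma_pN_per_nm = params$sigma,
    Pi_pN_per_nm2 = params$Pi, C0_per_nm = params$C0,
    Gamma_pN_nm = params$Gamma, R0_nm = params$R0),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_params_json
#' @export
read_params_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  model_params(kappa = j$kappa_pN_nm, sigma = j$sigma_pN_per_nm,
               Pi = j$Pi_pN_per_nm2, C0 = j$C0_per_nm,
               Gamma = if (!is.null(j$Gamma_pN_nm)) j$Gamma_pN_nm else 0,
               R0 = if (!is.null(j$R0_nm) && !is.na(j$R0_nm)) j$R0_nm
                    else NA_real_)
}

#' Read and write axisymmetric profiles as CSV
#'
#' Header `s_nm,r_nm,z_nm,psi_rad`.
#'
#' @param profile a [shape_profile].
#' @param path file path.
#' @return `read_profile_csv` returns a [shape_profile].
#' @export
write_profile_csv <- function(profile, path) {
  stopifnot(inherits(profile, "shape_profile"))
  df <- data.frame(s_nm = profile$s, r_nm = profile$r, z_nm = profile$z,
                   psi_rad = profile$psi)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile_csv
#' @export
read_profile_csv <- function(path) {
  df <- utils::read.csv(path)
  shape_profile(df$s_nm, df$r_nm, df$z_nm, df$psi_rad, check = FALSE)
}

#' Read and write traced contours as CSV
#'
#' Header `x_nm,y_nm`.
#'
#' @param contour a [contour2d].
#' @param path file path.
#' @return `read_contour_csv` returns a [contour2d].
#' @export
write_contour_csv <- function(contour, path) {
  stopifnot(inherits(contour, "contour2d"))
  utils::write.csv(data.frame(x_nm = contour$x, y_nm = contour$y), path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_contour_csv
#' @export
read_contour_csv <- function(path) {
  df <- utils::read.csv(path)
  contour2d(df$x_nm, df$y_nm)
}

#' Write a force-length curve as CSV
#'
#' Columns `branch_id,L_nm,fa_pN,E_pNnm,neck_nm,stable`.
#'
#' @param curve a [trace_branch] result.
#' @param path file path.
#' @export
write_curve_csv <- function(curve, path) {
  stopifnot(inherits(curve, "force_length_curve"))
  b <- curve$branches
  utils::write.csv(b[, c("branch_id", "L_nm", "fa_pN", "E_pNnm", "neck_nm",
                         "stable")], path, row.names = FALSE)
  invisible(path)
}

#' Write a shape solution (JSON scalars + profile CSV)
#'
#' @param solution a `shape_solution`.
#' @param stem output path stem; writes `<stem>.json` and
#'   `<stem>_profile.csv`.
#' @export
write_solution <- function(solution, stem) {
  stopifnot(inherits(solution, "shape_solution"))
  sc <- derived_scales(solution$params)
  jsonlite::write_json(list(
    params = list(kappa_pN_nm = solution$params$kappa,
                  sigma_pN_per_nm = solution$params$sigma,
                  Pi_pN_per_nm2 = solution$params$Pi,
                  C0_per_nm = solution$params$C0,
                  Gamma_pN_nm = solution$params$Gamma,
                  R0_nm = solution$params$R0),
    scales = sc[c("R_Pi", "f_Pi")],
    L_nm = solution$L, fa_pN = solution$f_a,
    observables = solution$observables,
    energies = unclass(solution$energies),
    residual = solution$residual,
    package_version = as.character(utils::packageVersion("endomech"))),
    paste0(stem, ".json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_profile_csv(solution$profile, paste0(stem, "_profile.csv"))
  invisible(stem)
}

#' Write a stability report as JSON
#'
#' @param report a [classify_regime] result.
#' @param path file path.
#' @export
write_stability_json <- function(report, path) {
  stopifnot(inherits(report, "stability_report"))
  jsonlite::write_json(list(
    regime = report$regime, sigma_pN_per_nm = report$sigma,
    C0_per_nm = report$C0,
    C0_star_per_nm = report$C0_star,
    C0_starstar_per_nm = report$C0_starstar,
    interval_nm = report$interval_nm,
    package_version = as.character(utils::packageVersion("endomech"))),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read and write rectified profiles as CSV
#'
#' Header `z_nm,r_nm` (apex to base order).
#'
#' @param profile a [rectify_contour] result (or data frame with `z`, `r`).
#' @param path file path.
#' @return `read_rectified_csv` returns a `rectified_profile` data frame.
#' @export
write_rectified_csv <- function(profile, path) {
  stopifnot(all(c("z", "r") %in% names(profile)))
  utils::write.csv(data.frame(z_nm = profile$z, r_nm = profile$r), path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_rectified_csv
#' @export
read_rectified_csv <- function(path) {
  df <- utils::read.csv(path)
  out <- data.frame(t = seq(0, 1, length.out = nrow(df)),
                    r = df$r_nm, z = df$z_nm)
  attr(out, "L") <- max(df$z_nm)
  class(out) <- c("rectified_profile", "data.frame")
  out
}
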