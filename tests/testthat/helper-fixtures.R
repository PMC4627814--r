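# Shared fixtures: kappa = 160 pN nm (40 kBT), Pi = 1 pN/nm^2, so
# R_Pi = 80^(1/3) = 4.3089 nm and f_Pi = 4 pi Pi R_Pi^2 = 233.3 pN.
RPI <- (160 / 2)^(1 / 3)

base_params <- function(c0_nd = 0, sig_nd = 0, Gam_rel = 0, rho0_nd = 1) {
  model_params(kappa = 160, sigma = sig_nd * 160 / RPI^2, Pi = 1,
               C0 = c0_nd / RPI, Gamma = Gam_rel * 160,
               R0 = if (Gam_rel > 0) rho0_nd * RPI else NA_real_)
}

FPI <- derived_scales(base_params())$f_Pi

# analytic spherical-cap profile (radius R, height h), apex up
cap_profile <- function(R, h, n = 400) {
  smax <- R * acos(1 - h / R)
  s <- seq(0, smax, length.out = n)
  shape_profile(s = s, r = R * sin(s / R), z = h - R * (1 - cos(s / R)),
                psi = s / R, check = FALSE)
}

# full-sphere profile resting on the wall plane
sphere_profile <- function(R, n = 800) {
  s <- seq(0, pi * R, length.out = n)
  shape_profile(s = s, r = R * sin(s / R), z = R * (1 + cos(s / R)),
                psi = s / R, check = FALSE)
}

cylinder_profile <- function(R, len, n = 400) {
  s <- seq(0, len, length.out = n)
  shape_profile(s = s, r = rep(R, n), z = len - s,
                psi = rep(pi / 2, n), check = FALSE)
}
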