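---
title: "Membrane mechanics of endocytosis under turgor pressure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Membrane mechanics of endocytosis under turgor pressure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(endomech)
```

## The physical problem

In walled cells such as budding and fission yeast, turgor pressure
$\Pi \sim 0.2$–$1\,\mathrm{pN/nm^2}$ presses the plasma membrane against the
cell wall.  During endocytosis the actin machinery must pull a membrane
invagination of height up to $\sim 120$ nm away from the wall against this
pressure, against the bending rigidity $\kappa$ of the coated membrane, and
against membrane tension $\sigma$.  `endomech` models the invagination as an
axisymmetric Helfrich surface pulled by an apical point force $f_a$,

$$
\mathcal F \;=\; \int_S \left[\frac{\kappa}{2}\,(C - C_0)^2 + \sigma\right]
\mathrm dS \;+\; \Pi V \;-\; f_a L ,
$$

where $C = 1/R_1 + 1/R_2$ is the total curvature, $C_0$ an isotropic
spontaneous curvature imposed by coat proteins, $S$ the detached membrane
area, $V$ the volume enclosed between membrane and wall, and $L$ the height
of the apex.  Crescent-shaped (BAR-domain) coat proteins add an anisotropic
term that penalizes deviations of the *azimuthal* principal curvature
$\sin\psi/r$ from a preferred $1/R_0$, with rigidity $\Gamma$.

Because the quasi-static relaxation time $L\eta_m/f \sim 10\,\mu s$ is
orders of magnitude below the seconds-long duration of an endocytic event
(`quasistatic_timescale()`), every stage is an equilibrium shape: the
force-height relation of the *static* family of shapes is the whole story.

## Scales and nondimensionalization

Pressure and rigidity select the invagination width
$R_\Pi = (\kappa/2\Pi)^{1/3}$ and the force scale
$f_\Pi = 4\pi\Pi R_\Pi^2 = 2\pi\kappa/R_\Pi$.  Internally everything is
nondimensional — lengths in $R_\Pi$, forces in $f_\Pi$, energies in
$2\pi\kappa$, with $\tilde\sigma = \sigma R_\Pi^2/\kappa$,
$\tilde C_0 = C_0 R_\Pi$, $\tilde\Gamma = \Gamma/\kappa$ — so results depend
on $\kappa$ and $\Pi$ only through $R_\Pi$.  `solve_shape()` verifies this
scale invariance in the test suite by solving at $(\kappa,\Pi)$ and
$(c\kappa, c\Pi)$.

```{r scales}
p <- model_params(kappa = 160, sigma = 0, Pi = 1, C0 = 0.4 / (80)^(1/3))
derived_scales(p)
```

## The boundary-value problem

Stationarity of $\mathcal F$ for axisymmetric shapes parametrized by
arclength $s$ (tangent angle $\psi$, radius $r$, height $z$, with
$r' = \cos\psi$, $z' = -\sin\psi$ from apex to base) gives a Hamiltonian
system of first-order equations for
$(\psi, r, h, M, \nu)$, where $M = \kappa\, r\,(C - C_0)$ is the bending
momentum and $\nu$ the multiplier conjugate to $r$.  Two first integrals
organize the solution:

* the **axial force**: the multiplier conjugate to height is constant and
  equals $-f_a$ — the point force applied at the apex is transmitted through
  every circle of latitude;
* the **free-arclength Hamiltonian** $H \equiv 0$, which fixes
  $\nu(0) = 0$ at the apex.

**Boundary conditions.**  At the apex: $r = 0$ with regularity and the
point-force balance.  At the contact line (free radius $r_c$): $z = 0$,
$\psi = 0$, and a *detachment condition* on the meridional curvature.
Because the energy integrals run over the detached surface only, a flat
annulus of detached membrane still costs
$e_0 = \kappa C_0^2/2 + \sigma$ per unit area relative to the attached
state; the contact line therefore behaves exactly like adhesion of strength
$e_0$, and the natural boundary condition is the classical curvature jump

$$
\left.\frac{\mathrm d\psi}{\mathrm d s}\right|_{s=\Sigma}
  = -\sqrt{C_0^2 + 2\sigma/\kappa},
$$

the membrane curving away from the wall.  Two facts pin this choice down
numerically: (i) the independent energy minimizer (below) produces exactly
this end slope as its natural boundary condition, and (ii) the $L \to 0$
limit of the traced apical force then reproduces the analytic initiation
force $f_0 = 4\pi\kappa\sqrt{C_0^2 + 2\sigma/\kappa}$ (which reduces to
$4\pi\kappa C_0$ at $\sigma = 0$) to better than $1\%$ — this is the
point-force detachment force from an adhesive substrate.  With
$C_0 = \sigma = 0$ the condition degenerates to simple curvature
continuity.

For the BAR term we take the flat *coated* state as the reference: BAR
coverage is uniform over the membrane, so its flat-state penalty
$\Gamma/(2R_0^2)$ is carried by attached and detached membrane alike, is
subtracted over the projected contact disk (energy component `E_bar_ref`),
and does not enter the detachment jump.  We initially implemented the
alternative (counting the BAR flat-state penalty as detachable energy);
this produced a strong spurious adhesion $\Gamma/(2R_0^2)$ that drove
almost-closed necks at $\Gamma = \kappa$, contradicting the stabilizing
role of BAR coats, and was abandoned.

**The point-force apex.**  A point force on a fluid membrane makes the
meridional curvature weakly singular at the apex (logarithmic for
$\Gamma = 0$; a $s^{\tilde\Gamma/2}$ power mode for $\Gamma > 0$).  The
solver starts the integration a small cut-off $\varepsilon$ from the apex
($\varepsilon = 10^{-6} R_\Pi$, enlarged to at most
$5\times10^{-3} R_\Pi$ for $\Gamma > 0$ where the power mode would
otherwise make shooting ill-conditioned).  The plateau force changes by
$< 4\times10^{-4}$ relative when $\varepsilon$ varies by two decades, so
the cut-off is immaterial at reported precision.

**Shooting and multiple shooting.**  The unknowns are the apex curvature
$u_0$, the force $\tilde f$ (when $L$ is imposed) and the free total
arclength $\Sigma$; residuals are the three contact-line conditions.  A
damped Newton iteration with finite-difference Jacobian solves the
$3\times3$ system (RK4 integration of the ODE system in compiled code,
$\ge 300$ steps per $R_\Pi$).  Shapes with narrow necks amplify shooting
errors exponentially, so the solver upgrades automatically to two-segment
multiple shooting — the full 7-component state at a junction placed at the
neck joins the unknown vector — which tracks necks down to the closure
threshold.  Heterogeneous rigidity $\kappa(A)$ (stiff clathrin-coated cap,
soft base) adds one state (accumulated area) and one multiplier, with the
cap extent measured in membrane area and the arclength transition width $w$
converted to an area width $2\pi R_\Pi w$.

## The independent oracle

`direct_minimization()` minimizes the *discretized* energy over
tangent-angle profiles at fixed height (midpoint quadrature, augmented
Lagrangian for the height constraint, L-BFGS-B, one-sided wall penalty for
$z \ge 0$ and a no-self-overlap penalty).  It shares no code path, no
discretization and no boundary-condition implementation with the shooting
solver, so their agreement — better than $2\%$ of $R_\Pi$ pointwise and
$1\%$ in energy over the tested $(\tilde C_0, \tilde\sigma, L)$ grid, and
in practice $\sim 10^{-4}$ — cross-validates both.  The minimizer also
serves as the cold-start generator for the shooting solver and arbitrates
boundary-condition questions (it selects the negative curvature-jump root).

## Force–length curves and the shape instability

`trace_branch()` follows the equilibrium family by pseudo-arclength
continuation in $(\theta, L)$ with secant predictors, adaptive steps, fold
detection by reversal of $L$, and seeding from both the nearly flat state
and the long-tube asymptote (`tube_limit()`, the 1-D minimization of the
per-length tube energy, provides the plateau oracle:
$f \to 0.75 f_\Pi$, radius $\to R_\Pi$ for $\tilde C_0 = \sigma = 0$).

```{r curve, eval = FALSE}
cv <- trace_branch(p)          # C0 = 0.4 / R_Pi
plot(cv)
```

At the fitted spontaneous curvature $\tilde C_0 = 0.4$ the curve starts at
the initiation force $0.8 f_\Pi$, peaks near $L \approx R_\Pi$ at
$\approx 1.29 f_\Pi$ (initiation is $\approx 62\%$ of the maximum), dips to
a shallow minimum near $L \approx 3 R_\Pi$ and approaches the tube plateau
— the snap-through profile that makes endocytosis hard to start and easy to
finish.

`classify_regime()` reads the branch topology: a single fold-free branch
(*smooth*), two branches overlapping in height (*hysteresis*, e.g.
$\tilde C_0 = 0.45$), or disjoint supports with heights that admit no
equilibrium (*gap*, e.g. $\tilde C_0 = 1$).  `find_thresholds()` locates
the regime boundaries $C_0^*$ and $C_0^{**}$ by bisection (tolerance
$10^{-2}/R_\Pi$), `critical_curvature_at_length()` finds the curvature
$C_0^+(L)$ at which the neck radius crosses the closure threshold
$\epsilon = 10^{-2} R_\Pi$ (below which the continuum description is
meaningless and the solver becomes singular — our numerical proxy for a
zero-radius neck), and `energy_crossing()` tabulates how the
tubular-to-spheroidal transition trades bending energy down against
pressure energy up.

Two honest caveats from our reconstruction of the model:

* at $C_0 = 0$ the traced curve shows a finite tether-formation force
  overshoot before the plateau (its minimum is still at $L = 0$);
* at $\Gamma = \kappa$, $R_0 = R_\Pi$, $C_0 = 1/R_\Pi$ the BAR coat removes
  the no-equilibrium gap and keeps necks open (scission then requires
  removing the coat, `scission_test()`), but the energy-minimizing family
  still switches first-order between an open-neck and a narrow-neck shape
  over a small height window, so the traced curve is not strictly
  fold-free.  Both behaviours are confirmed by the independent minimizer,
  i.e. they are properties of the model as formulated here, with our
  contact-line conventions, not solver artifacts.

## Fitting membrane profiles

Real input data are traced 2D contours.  `rectify_contour()` estimates the
symmetry axis as the least-squares midline of left/right points matched by
*normalized arclength* from the apex (robust to overhanging necks, where
the radius is multivalued in height), averages the two sides and reports an
asymmetry score.  `fit_profile()` then minimizes the symmetric mean
closest-point distance (point-to-polyline, clipped 0.5 nm above the wall so
unequal contact radii do not dominate) between each observed profile and
the model equilibrium of equal height, over $(R_\Pi, \tilde\sigma,
\tilde C_0)$; the apical force per profile is implied.  The search is a
coarse grid (default $8\times8\times8$ over $R_\Pi \in [5, 40]$ nm,
$\tilde\sigma \in [0, 0.3]$, $\tilde C_0 \in [0, 1]$) followed by
Nelder–Mead refinement, with a solver cache reusable across fits.  All grid
points within $1.1\times$ the best residual form the *degenerate set* —
profiles constrain $R_\Pi$ well but $\tilde\sigma$ and $\tilde C_0$ only
weakly, and the reported parameter ranges make that explicit.
`fit_report()` converts to physical parameters at an assumed pressure
($\kappa = 2\Pi R_\Pi^3$, etc.).

## Synthetic data: what it does and does not emulate

No tomography profiles are deposited, so `synthetic_spec()` /
`generate_contour()` / `make_benchmark_suite()` generate pseudo-tomography
contours from the forward model: defaults $R_\Pi = 20$ nm,
$\tilde C_0 = 0.4$, $\tilde\sigma = 0$ (the fitted parameter scale, which
gives tip radii within a few percent of the measured $\sim 12$ nm), heights
$10$–$100$ nm, point spacing 3 nm, isotropic Gaussian tracing noise of
SD 1 nm (sub-pixel at tomography scale), a 2 nm axis offset and a single
sinusoidal skew mode of 1.5 nm emulating tilt/tracing artifacts.  The
generator exercises everything the rectification and fitting stages assume
— but it draws from the *same* shape family that is being fitted, with
idealized noise.  Passing recovery tests therefore demonstrates that the
pipeline is consistent and well-conditioned at realistic noise levels, not
that the continuum model describes real membranes; and real tomograms add
segmentation bias, anisotropic point densities and missing-wedge artifacts
that the generator deliberately omits.

## Numerical choices

* BVP residual tolerance $10^{-9}$ (nondimensional); the conserved
  Hamiltonian is monitored as an accuracy diagnostic.
* Continuation steps adaptive in $[10^{-3}, 0.25]$; branches seeded from
  $L \approx 0.1 R_\Pi$ and from the tube asymptote; neck closure ends a
  branch.
* Quadrature for `evaluate_energy()`: composite trapezoid; solution
  profiles carry $\ge 300$ nodes per $R_\Pi$; a refinement study is part of
  the test suite.
* Problem sizes: regime sweeps use $L \in [0, 6 R_\Pi]$ with at most a few
  hundred solves; oracle comparisons use 150-interval discretizations;
  recovery studies use 20 seeded replicates of 60 nm contours.  A full
  test-suite run solves a few thousand boundary-value problems.
* Degenerate inputs: non-convergent targets raise conditions of class
  `endomech_solver_failure`; heights in the gap (or with necks below the
  closure threshold) raise `endomech_no_equilibrium` — the latter is a
  physical statement, not an error in the usual sense.

## Known limitations

* The contact-line conditions are our reconstruction (validated by the
  minimizer's natural boundary conditions and the analytic initiation
  force); other conventions at the rim would shift instability thresholds
  somewhat.
* Uniform coat coverage: $C_0$, $\Gamma$ act over the whole detached
  membrane.  Rvs167 localizes to the neck in reality.
* No non-axisymmetric modes, no dynamics, no explicit actin network; the
  apical force is a point force, and forces are reported as requirements on
  the machinery, not predictions of it.
* Continuum mechanics at nm scales: necks below $\sim 0.1$ nm are treated
  as scission, and sub-nm features of fitted profiles carry no meaning.
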