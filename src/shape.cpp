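// Axisymmetric shape equations for a pressurized Helfrich membrane pulled by
// an apical point force, in nondimensional variables: lengths in units of the
// pressure-rigidity scale R_Pi = (kappa/2Pi)^(1/3), rigidity relative to the
// (tip) rigidity kappa, reduced energies in units of 2*pi*kappa, forces in
// units of f_Pi = 2*pi*kappa/R_Pi.
//
// State vector (11):
//   0 psi    tangent angle (0 at apex, 0 at contact line)
//   1 r      radius
//   2 h      depth below apex (h' = sin psi); height L = h(Sigma)
//   3 M      bending momentum kap(a) * r * w,  w = psi' + sin(psi)/r - c0
//   4 nu     multiplier conjugate to r (nu(0) = 0 from the free-arclength
//            first integral H = 0)
//   5 a      reduced detached area  int r ds   (physical S = 2 pi a R_Pi^2)
//   6 mu     multiplier conjugate to a (identically 0 when rigidity uniform)
//   7 ebend  int kap(a) (r/2) w^2 ds
//   8 ebar   int Gam (r/2) b^2 ds,   b = sin(psi)/r - 1/rho0
//   9 vol    int (r^2/2) sin(psi) ds (physical V = 2 pi vol R_Pi^3)
//  10 H      running value of the first integral (accuracy diagnostic only;
//            stored, not integrated)

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

struct ShapePars {
  double c0;        // spontaneous curvature * R_Pi
  double sig;       // sigma R_Pi^2 / kappa
  double Gam;       // Gamma / kappa
  double rho0inv;   // R_Pi / R0 (0 when Gam == 0)
  double ftil;      // apical force / f_Pi (the constant axial multiplier)
  bool   het;       // heterogeneous rigidity?
  double kmin;      // kappa_min / kappa_tip
  double atip;      // stiff-cap extent in reduced area units
  double wa;        // transition width in reduced area units
};

static inline double kap_of_a(const ShapePars& p, double a) {
  if (!p.het) return 1.0;
  return p.kmin + (1.0 - p.kmin) * 0.5 * (1.0 - std::tanh((a - p.atip) / p.wa));
}

static inline double dkap_da(const ShapePars& p, double a) {
  if (!p.het) return 0.0;
  double t = std::tanh((a - p.atip) / p.wa);
  return -(1.0 - p.kmin) * 0.5 * (1.0 - t * t) / p.wa;
}

static inline void rhs(const ShapePars& p, const double* y, double* dy) {
  double psi = y[0], r = y[1], M = y[3], nu = y[4], a = y[5], mu = y[6];
  double cp = std::cos(psi), sp = std::sin(psi);
  double kap = kap_of_a(p, a);
  double w   = M / (kap * r);
  double spr = sp / r;
  double u   = w - spr + p.c0;
  double b   = spr - p.rho0inv;
  dy[0] = u;
  dy[1] = cp;
  dy[2] = sp;
  dy[3] = (kap * w + p.Gam * b + 0.25 * r * r - p.ftil) * cp + nu * sp;
  dy[4] = kap * (0.5 * w * w - w * spr) + p.Gam * (0.5 * b * b - b * spr)
          + p.sig + 0.5 * r * sp - mu;
  dy[5] = r;
  dy[6] = dkap_da(p, a) * 0.5 * r * w * w;
  dy[7] = kap * 0.5 * r * w * w;
  dy[8] = p.Gam * 0.5 * r * b * b;
  dy[9] = 0.5 * r * r * sp;
  dy[10] = 0.0;
}

static inline void rk4_step(const ShapePars& p, double* y, double hstep) {
  const int n = 10;
  double k1[11], k2[11], k3[11], k4[11], yt[11];
  rhs(p, y, k1);
  for (int i = 0; i < n; ++i) yt[i] = y[i] + 0.5 * hstep * k1[i];
  rhs(p, yt, k2);
  for (int i = 0; i < n; ++i) yt[i] = y[i] + 0.5 * hstep * k2[i];
  rhs(p, yt, k3);
  for (int i = 0; i < n; ++i) yt[i] = y[i] + hstep * k3[i];
  rhs(p, yt, k4);
  for (int i = 0; i < n; ++i)
    y[i] += hstep / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
}

static inline double hamiltonian(const ShapePars& p, const double* y) {
  double psi = y[0], r = y[1], M = y[3], nu = y[4], a = y[5], mu = y[6];
  double cp = std::cos(psi), sp = std::sin(psi);
  double kap = kap_of_a(p, a);
  double w = M / (kap * r);
  double u = w - sp / r + p.c0;
  double b = sp / r - p.rho0inv;
  return M * u + nu * cp + p.ftil * sp + mu * r
       - (kap * 0.5 * r * w * w + p.Gam * 0.5 * r * b * b + p.sig * r
          + 0.25 * r * r * sp);
}

// Series start a small distance eps from the apex (regular expansion; the
// point force introduces a weak logarithmic curvature correction that the
// integrator picks up for s > eps).
static void apex_state(const ShapePars& p, double u0, double mu0, double eps,
                       double* y) {
  double w0 = 2.0 * u0 - p.c0;
  double b0 = u0 - p.rho0inv;
  double kap0 = kap_of_a(p, 0.0);
  y[0] = u0 * eps;
  y[1] = eps - u0 * u0 * eps * eps * eps / 6.0;
  y[2] = 0.5 * u0 * eps * eps;
  y[3] = kap0 * y[1] * w0;
  double nup0 = kap0 * (0.5 * w0 * w0 - w0 * u0)
              + p.Gam * (0.5 * b0 * b0 - b0 * u0) + p.sig - mu0;
  y[4] = nup0 * eps;
  y[5] = 0.5 * eps * eps;
  y[6] = mu0;
  y[7] = kap0 * 0.25 * w0 * w0 * eps * eps;
  y[8] = p.Gam * 0.25 * b0 * b0 * eps * eps;
  y[9] = 0.0;
  y[10] = 0.0;
}

static ShapePars pars_from_list(List pars, double ftil) {
  ShapePars p;
  p.c0 = as<double>(pars["c0"]);
  p.sig = as<double>(pars["sig"]);
  p.Gam = as<double>(pars["Gam"]);
  p.rho0inv = as<double>(pars["rho0inv"]);
  p.ftil = ftil;
  p.het = as<bool>(pars["het"]);
  p.kmin = p.het ? as<double>(pars["kmin"]) : 1.0;
  p.atip = p.het ? as<double>(pars["atip"]) : 1.0;
  p.wa = p.het ? as<double>(pars["wa"]) : 1.0;
  return p;
}

// Integrate from the apex to total arclength Sigma.  Returns the final state
// (with H stored in slot 10) and optionally the trajectory on the uniform
// phase of the grid plus the graded near-apex nodes.
// [[Rcpp::export]]
List shape_integrate_cpp(double u0, double ftil, double Sigma, double mu0,
                         List pars, int nper = 300, bool traj = false,
                         double eps = 1e-6) {
  ShapePars p = pars_from_list(pars, ftil);
  double y[11];
  apex_state(p, u0, mu0, eps, y);

  double s = eps;
  double s1 = std::min(0.02, 0.2 * Sigma);   // end of graded apex phase
  int n1 = 80;                                // graded steps
  int n2 = std::max(200, (int)std::ceil(nper * (Sigma - s1)));
  double rmin = y[1]; double rmin_s = s;
  double neck = -1.0; double prev_r = y[1];   // interior neck: min r on descents

  std::vector<double> out;
  int ncol = 13;
  auto record = [&](double scur, const double* yy) {
    if (!traj) return;
    double kap = kap_of_a(p, yy[5]);
    double w = yy[3] / (kap * yy[1]);
    double u = w - std::sin(yy[0]) / yy[1] + p.c0;
    out.push_back(scur);
    for (int i = 0; i < 10; ++i) out.push_back(yy[i]);
    out.push_back(u);
    out.push_back(kap);
  };

  record(s, y);
  // Phase 1: geometric steps away from the apex.
  double g = std::pow(s1 / eps, 1.0 / n1);
  for (int k = 0; k < n1; ++k) {
    double snext = s * g;
    rk4_step(p, y, snext - s);
    s = snext;
    if (y[1] < rmin) { rmin = y[1]; rmin_s = s; }
    if (k % 8 == 7) record(s, y);
  }
  // Phase 2: uniform steps to Sigma.
  double hstep = (Sigma - s) / n2;
  for (int k = 0; k < n2; ++k) {
    rk4_step(p, y, hstep);
    s += hstep;
    if (!std::isfinite(y[0]) || !std::isfinite(y[3]) || y[1] <= 0.0) {
      return List::create(_["ok"] = false, _["s"] = s);
    }
    if (y[1] < rmin) { rmin = y[1]; rmin_s = s; }
    if (y[1] < prev_r && (neck < 0.0 || y[1] < neck)) neck = y[1];
    prev_r = y[1];
    record(s, y);
  }
  y[10] = hamiltonian(p, y);

  NumericVector fin(11);
  for (int i = 0; i < 11; ++i) fin[i] = y[i];
  double kap_end = kap_of_a(p, y[5]);
  double w_end = y[3] / (kap_end * y[1]);
  double u_end = w_end - std::sin(y[0]) / y[1] + p.c0;

  List res = List::create(
    _["ok"] = true, _["final"] = fin, _["u_end"] = u_end,
    _["kap_end"] = kap_end, _["rmin"] = rmin, _["rmin_s"] = rmin_s,
    _["neck"] = neck);
  if (traj) {
    int nrow = out.size() / ncol;
    NumericMatrix m(nrow, ncol);
    for (int i = 0; i < nrow; ++i)
      for (int j = 0; j < ncol; ++j) m(i, j) = out[i * ncol + j];
    colnames(m) = CharacterVector::create("s", "psi", "r", "h", "M", "nu",
      "a", "mu", "ebend", "ebar", "vol", "u", "kap");
    res["traj"] = m;
  }
  return res;
}

// Integrate a segment from an arbitrary interior state (multiple shooting).
// y0 carries the 10 integrated states (slot 10 ignored on input).
// [[Rcpp::export]]
List shape_integrate_from_cpp(NumericVector y0, double slen, double ftil,
                              List pars, int nper = 300, bool traj = false,
                              double s_offset = 0.0) {
  ShapePars p = pars_from_list(pars, ftil);
  double y[11];
  for (int i = 0; i < 11; ++i) y[i] = y0[i];
  int n2 = std::max(150, (int)std::ceil(nper * slen));
  double s = s_offset;
  double rmin = y[1];
  double neck = -1.0; double prev_r = y[1];

  std::vector<double> out;
  int ncol = 13;
  auto record = [&](double scur, const double* yy) {
    if (!traj) return;
    double kap = kap_of_a(p, yy[5]);
    double w = yy[3] / (kap * yy[1]);
    double u = w - std::sin(yy[0]) / yy[1] + p.c0;
    out.push_back(scur);
    for (int i = 0; i < 10; ++i) out.push_back(yy[i]);
    out.push_back(u);
    out.push_back(kap);
  };
  record(s, y);
  double hstep = slen / n2;
  for (int k = 0; k < n2; ++k) {
    rk4_step(p, y, hstep);
    s += hstep;
    if (!std::isfinite(y[0]) || !std::isfinite(y[3]) || y[1] <= 0.0)
      return List::create(_["ok"] = false, _["s"] = s);
    if (y[1] < rmin) rmin = y[1];
    if (y[1] < prev_r && (neck < 0.0 || y[1] < neck)) neck = y[1];
    prev_r = y[1];
    record(s, y);
  }
  y[10] = hamiltonian(p, y);
  NumericVector fin(11);
  for (int i = 0; i < 11; ++i) fin[i] = y[i];
  double kap_end = kap_of_a(p, y[5]);
  double w_end = y[3] / (kap_end * y[1]);
  double u_end = w_end - std::sin(y[0]) / y[1] + p.c0;
  List res = List::create(
    _["ok"] = true, _["final"] = fin, _["u_end"] = u_end,
    _["kap_end"] = kap_end, _["rmin"] = rmin, _["neck"] = neck);
  if (traj) {
    int nrow = out.size() / ncol;
    NumericMatrix m(nrow, ncol);
    for (int i = 0; i < nrow; ++i)
      for (int j = 0; j < ncol; ++j) m(i, j) = out[i * ncol + j];
    colnames(m) = CharacterVector::create("s", "psi", "r", "h", "M", "nu",
      "a", "mu", "ebend", "ebar", "vol", "u", "kap");
    res["traj"] = m;
  }
  return res;
}

// ---------------------------------------------------------------------------
// Discretized energy for the independent direct-minimization oracle.
// Profile parametrized by the tangent angle at N+1 equally spaced arclength
// nodes (psi_0 = psi_N = 0); r obtained by trapezoidal cumulation of cos psi;
// integrand evaluated at interval midpoints.  Returns the reduced excess
// energy (units 2 pi kappa), measured relative to the flat attached state,
// together with the height and geometric totals.
// Lwall/penz: one-sided wall penalty keeping the membrane above the wall
// plane (depth below apex may not exceed the target height).
static void discrete_energy(const ShapePars& p, const std::vector<double>& psi,
                            double Sigma, double Lwall, double penz,
                            double* outv) {
  int N = (int)psi.size() - 1;
  double hstep = Sigma / N;
  double E = 0.0, height = 0.0, area = 0.0, vol = 0.0;
  double ebend = 0.0, ebar = 0.0;
  double r = 0.0, a = 0.0;
  double barrier = 0.0, hmax = 0.0;
  for (int i = 0; i < N; ++i) {
    double pm = 0.5 * (psi[i] + psi[i + 1]);
    double u = (psi[i + 1] - psi[i]) / hstep;
    double sm = std::sin(pm);
    double rn = r + 0.5 * hstep * (std::cos(psi[i]) + std::cos(psi[i + 1]));
    double rm = 0.5 * (r + rn);
    if (rm < 1e-9) { barrier += 1e6 * (1e-9 - rm) * (1e-9 - rm); rm = 1e-9; }
    double am = a + 0.5 * hstep * rm;
    double kap = kap_of_a(p, am);
    double w = u + sm / rm - p.c0;
    double b = sm / rm - p.rho0inv;
    ebend += hstep * kap * 0.5 * rm * w * w;
    ebar  += hstep * p.Gam * 0.5 * rm * b * b;
    area  += hstep * rm;
    vol   += hstep * 0.5 * rm * rm * sm;
    height += hstep * sm;
    if (penz > 0.0) {
      // wall: the membrane may not descend below the wall plane
      if (height > Lwall) {
        double ex = height - Lwall;
        barrier += penz * ex * ex * hstep;
      }
      // no self-overlap: depth is monotone along arclength up to small
      // ripples (slack 0.2) -- forbids double-covered sheets that would
      // otherwise harvest negative pressure volume
      if (height < hmax - 0.2) {
        double ex = hmax - 0.2 - height;
        barrier += penz * ex * ex * hstep;
      }
      if (height > hmax) hmax = height;
    }
    r = rn;
    a += hstep * rm;
  }
  // the BAR coat covers attached membrane too: measure its energy relative
  // to the flat coated state (projected-disk reference)
  E = ebend + ebar + p.sig * area + 0.5 * vol
    - p.Gam * 0.5 * p.rho0inv * p.rho0inv * 0.5 * r * r + barrier;
  outv[0] = E; outv[1] = height; outv[2] = r; outv[3] = ebend;
  outv[4] = ebar; outv[5] = area; outv[6] = vol;
}

// x = (psi_1, ..., psi_{N-1}, Sigma)
// [[Rcpp::export]]
NumericVector discrete_energy_cpp(NumericVector x, List pars) {
  ShapePars p = pars_from_list(pars, 0.0);
  int N = x.size();                 // N-1 interior nodes + Sigma -> N intervals
  std::vector<double> psi(N + 1);
  psi[0] = 0.0; psi[N] = 0.0;
  for (int i = 1; i < N; ++i) psi[i] = x[i - 1];
  double Sigma = x[N - 1];
  double outv[7];
  discrete_energy(p, psi, Sigma, 0.0, 0.0, outv);
  NumericVector res(7);
  for (int i = 0; i < 7; ++i) res[i] = outv[i];
  res.names() = CharacterVector::create("E", "height", "r_end", "ebend",
                                        "ebar", "area", "vol");
  return res;
}

// Augmented-Lagrangian objective and central-difference gradient for the
// height-constrained minimization:  Phi = E + lam*(height-L) + pen/2*(...)^2.
static double phi_of(const ShapePars& p, std::vector<double>& psi, double Sigma,
                     double L, double lam, double pen) {
  double outv[7];
  discrete_energy(p, psi, Sigma, L, 5e4, outv);
  double c = outv[1] - L;
  return outv[0] + lam * c + 0.5 * pen * c * c + 1e-8 * Sigma * Sigma;
}

// [[Rcpp::export]]
double al_objective_cpp(NumericVector x, List pars, double L, double lam,
                        double pen) {
  ShapePars p = pars_from_list(pars, 0.0);
  int N = x.size();
  std::vector<double> psi(N + 1);
  psi[0] = 0.0; psi[N] = 0.0;
  for (int i = 1; i < N; ++i) psi[i] = x[i - 1];
  return phi_of(p, psi, x[N - 1], L, lam, pen);
}

// [[Rcpp::export]]
NumericVector al_gradient_cpp(NumericVector x, List pars, double L, double lam,
                              double pen, double dstep = 1e-6) {
  ShapePars p = pars_from_list(pars, 0.0);
  int N = x.size();
  std::vector<double> psi(N + 1);
  psi[0] = 0.0; psi[N] = 0.0;
  for (int i = 1; i < N; ++i) psi[i] = x[i - 1];
  double Sigma = x[N - 1];
  NumericVector g(N);
  for (int i = 1; i < N; ++i) {
    double keep = psi[i];
    psi[i] = keep + dstep;
    double fp = phi_of(p, psi, Sigma, L, lam, pen);
    psi[i] = keep - dstep;
    double fm = phi_of(p, psi, Sigma, L, lam, pen);
    psi[i] = keep;
    g[i - 1] = (fp - fm) / (2.0 * dstep);
  }
  double fp = phi_of(p, psi, Sigma + dstep, L, lam, pen);
  double fm = phi_of(p, psi, Sigma - dstep, L, lam, pen);
  g[N - 1] = (fp - fm) / (2.0 * dstep);
  return g;
}
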