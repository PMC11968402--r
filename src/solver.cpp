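#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Linear wave theory primitives
// ---------------------------------------------------------------------------

// Solve x*tanh(x) = y for x = k*h (Newton; f is monotone increasing and
// convex for x > 0 so the iteration is globally convergent from the guesses
// below). Relative tolerance ~1e-12, well inside the 1e-10 contract.
static double solve_kh(double y) {
  if (y <= 0.0) return 0.0;
  double x = (y > 1.0) ? y : std::sqrt(y);
  for (int i = 0; i < 100; ++i) {
    double t  = std::tanh(x);
    double f  = x * t - y;
    double fp = t + x * (1.0 - t * t);
    if (fp <= 0.0) break;
    double dx = f / fp;
    x -= dx;
    if (std::fabs(dx) <= 1e-13 * x) break;
  }
  return x;
}

static double wavenumber(double sigma, double h, double g) {
  return solve_kh(sigma * sigma * h / g) / h;
}

static double group_velocity_c(double sigma, double k, double h) {
  double kh = k * h;
  double s2 = std::sinh(2.0 * kh);          // inf for huge kh -> ratio 0
  double n  = 0.5 * (1.0 + 2.0 * kh / s2);
  return n * sigma / k;
}

// ---------------------------------------------------------------------------
// Battjes–Janssen fraction of breaking waves: solves (1-Q)/(-ln Q) = b^2,
// i.e. 1 - Q + b^2 ln Q = 0 on (0, b^2), with b = Hrms/Hmax.
// ---------------------------------------------------------------------------
static double qb_frac(double b) {
  if (b <= 0.3) return 0.0;                 // Q < ~3e-4: negligible
  if (b >= 1.0) return 1.0;
  double b2 = b * b;
  double q = std::exp(-(1.0 - b2) / b2);    // fixed-point warm start
  for (int i = 0; i < 8; ++i) q = std::exp((q - 1.0) / b2);
  for (int i = 0; i < 30; ++i) {            // Newton polish, guarded in (0, b2)
    double f  = 1.0 - q + b2 * std::log(q);
    double fp = -1.0 + b2 / q;
    double qn = q - f / fp;
    if (qn <= 0.0) qn = 0.5 * q;
    if (qn >= 1.0) qn = 0.5 * (q + 1.0);
    if (std::fabs(qn - q) < 1e-13) { q = qn; break; }
    q = qn;
  }
  return q;
}

// ---------------------------------------------------------------------------
// Dissipation source terms (all in W/m^2, bulk Hs formulation, E = rho g Hs^2/16)
// ---------------------------------------------------------------------------

static double eps_break_c(double hs, double h, double sigma, double gamma,
                          double rho, double g, double alpha_bj) {
  if (hs <= 0.0 || h <= 0.0) return 0.0;
  double hmax = gamma * h;
  double qb = qb_frac(hs / (M_SQRT2 * hmax));
  if (qb <= 0.0) return 0.0;
  double fmean = sigma / (2.0 * M_PI);
  return alpha_bj * 0.25 * qb * fmean * rho * g * hmax * hmax;
}

// Collins drag-law bottom friction with near-bed rms orbital velocity
// u_rms = sigma*Hs/(4 sinh kh): eps = rho*cf*sigma^3*Hs^3 / (64 sinh^3 kh).
static double eps_fric_c(double hs, double h, double k, double sigma,
                         double cf, double rho) {
  if (cf <= 0.0 || hs <= 0.0) return 0.0;
  double kh = k * h;
  if (kh > 50.0) return 0.0;
  double s = std::sinh(kh);
  return rho * cf * sigma * sigma * sigma * hs * hs * hs / (64.0 * s * s * s);
}

// Layered Mendez–Losada vegetation dissipation (7-layer form, Hs-based):
//   eps_v = sum_i  rho*Cd_i/(4 sqrt(2 pi)) * (g k / 2 sigma)^3 * f_i
//           * [ (sinh^3(k a_i h) - sinh^3(k a_{i-1} h))
//               + 3 (sinh(k a_i h) - sinh(k a_{i-1} h)) ]
//           / (3 k cosh^3(k h)) * Hs^3,   a_0 = 0, a_i = min(ztop_i, h)/h.
static double eps_veg_c(double hs, double k, double sigma, double h,
                        const double* ztop, const double* f, const double* cd,
                        int nl, double rho, double g) {
  if (hs <= 0.0 || nl == 0) return 0.0;
  double kh = k * h;
  if (kh > 50.0) return 0.0;  // vegetation never sits in effectively deep water
  double ch = std::cosh(kh);
  double pref = rho / (4.0 * std::sqrt(2.0 * M_PI))
              * std::pow(g * k / (2.0 * sigma), 3)
              * hs * hs * hs / (3.0 * k * ch * ch * ch);
  double tot = 0.0, sprev = 0.0, aprev = 0.0;
  for (int i = 0; i < nl; ++i) {
    double a = std::min(ztop[i], h) / h;
    if (a < aprev) a = aprev;
    if (a > 1.0) a = 1.0;
    double s = std::sinh(k * a * h);
    tot += cd[i] * f[i] * ((s * s * s - sprev * sprev * sprev) + 3.0 * (s - sprev));
    sprev = s;
    aprev = a;
  }
  return pref * tot;
}

// ---------------------------------------------------------------------------
// Vectorised exports of the primitives
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector dispersion_cpp(NumericVector sigma, NumericVector h, double g) {
  int n = std::max(sigma.size(), h.size());
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = wavenumber(sigma[i % sigma.size()], h[i % h.size()], g);
  return out;
}

// [[Rcpp::export]]
NumericVector eps_break_cpp(NumericVector hs, NumericVector h, NumericVector sigma,
                            double gamma, double rho, double g, double alpha_bj) {
  int n = std::max(hs.size(), std::max(h.size(), sigma.size()));
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = eps_break_c(hs[i % hs.size()], h[i % h.size()], sigma[i % sigma.size()],
                         gamma, rho, g, alpha_bj);
  return out;
}

// [[Rcpp::export]]
NumericVector eps_fric_cpp(NumericVector hs, NumericVector h, NumericVector k,
                           NumericVector sigma, NumericVector cf, double rho) {
  int n = std::max(hs.size(), std::max(h.size(), cf.size()));
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = eps_fric_c(hs[i % hs.size()], h[i % h.size()], k[i % k.size()],
                        sigma[i % sigma.size()], cf[i % cf.size()], rho);
  return out;
}

// [[Rcpp::export]]
NumericVector eps_veg_cpp(NumericVector hs, NumericVector k, NumericVector sigma,
                          NumericVector h, NumericVector ztop, NumericVector f,
                          NumericVector cd, double rho, double g) {
  int n = std::max(hs.size(), h.size());
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = eps_veg_c(hs[i % hs.size()], k[i % k.size()], sigma[i % sigma.size()],
                       h[i % h.size()], &ztop[0], &f[0], &cd[0], ztop.size(), rho, g);
  return out;
}

// [[Rcpp::export]]
NumericVector qb_cpp(NumericVector b) {
  NumericVector out(b.size());
  for (int i = 0; i < b.size(); ++i) out[i] = qb_frac(b[i]);
  return out;
}

// ---------------------------------------------------------------------------
// Stationary 1D bulk energy-flux marching solver:
//   d(E cg)/dx = -(eps_break + eps_fric + eps_veg),  E = rho g Hs^2 / 16,
// Heun (predictor-corrector) steps with adaptive halving when a step would
// drive the flux negative; exhausted substepping clamps to zero.
// veg_on is a per-cell weight in [0,1] (0 outside the forest).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List march_cpp(double hs0, double tp,
               NumericVector depth, NumericVector cf, NumericVector veg_on,
               NumericVector veg_ztop, NumericVector veg_f, NumericVector veg_cd,
               double dx, double gamma, double rho, double g,
               double dry, double alpha_bj) {
  int n = depth.size();
  NumericVector hs(n), eb(n), ef(n), ev(n), flux(n);
  double sigma = 2.0 * M_PI / tp;
  int nl = veg_ztop.size();
  const double* zt = nl ? &veg_ztop[0] : (double*)0;
  const double* fv = nl ? &veg_f[0] : (double*)0;
  const double* cd = nl ? &veg_cd[0] : (double*)0;

  auto eps_tot = [&](double h, double hsv, double cfv, double w,
                     double* peb, double* pef, double* pev) {
    double k = wavenumber(sigma, h, g);
    double a = eps_break_c(hsv, h, sigma, gamma, rho, g, alpha_bj);
    double b = eps_fric_c(hsv, h, k, sigma, cfv, rho);
    double c = (w > 0.0 && nl) ? w * eps_veg_c(hsv, k, sigma, h, zt, fv, cd, nl, rho, g)
                               : 0.0;
    if (peb) { *peb = a; *pef = b; *pev = c; }
    return a + b + c;
  };
  auto hs_of = [&](double F, double h) {
    double k = wavenumber(sigma, h, g);
    double cg = group_velocity_c(sigma, k, h);
    return std::sqrt(std::max(0.0, 16.0 * F / (rho * g * cg)));
  };
  auto flux_of = [&](double hsv, double h) {
    double k = wavenumber(sigma, h, g);
    double cg = group_velocity_c(sigma, k, h);
    return rho * g * hsv * hsv / 16.0 * cg;
  };
  // One transect step with adaptive substepping; depth/cf/veg weight
  // interpolated linearly between the two cells.
  auto step_flux = [&](double F, double hA, double hB, double cfA, double cfB,
                       double wA, double wB) {
    for (int nsub = 1; nsub <= 4096; nsub *= 2) {
      double ddx = dx / nsub, Fc = F;
      bool ok = true;
      for (int i = 0; i < nsub && ok; ++i) {
        double t0 = (double)i / nsub, t1 = (double)(i + 1) / nsub;
        double h0 = hA + (hB - hA) * t0, h1 = hA + (hB - hA) * t1;
        double c0 = cfA + (cfB - cfA) * t0, c1 = cfA + (cfB - cfA) * t1;
        double w0 = wA + (wB - wA) * t0, w1 = wA + (wB - wA) * t1;
        double e0 = eps_tot(h0, hs_of(Fc, h0), c0, w0, 0, 0, 0);
        double Fp = Fc - ddx * e0;
        if (Fp < 0.0) { ok = false; break; }
        double e1 = eps_tot(h1, hs_of(Fp, h1), c1, w1, 0, 0, 0);
        double Fn = Fc - 0.5 * ddx * (e0 + e1);
        if (Fn < 0.0) { ok = false; break; }
        Fc = Fn;
      }
      if (ok) return Fc;
    }
    return 0.0;
  };

  bool dead = (depth[0] <= dry);
  if (!dead) hs[0] = hs0;
  for (int j = 0; j < n; ++j) {
    if (dead || depth[j] <= dry) { dead = true; hs[j] = 0.0; continue; }
    flux[j] = flux_of(hs[j], depth[j]);
    eps_tot(depth[j], hs[j], cf[j], veg_on[j], &eb[j], &ef[j], &ev[j]);
    if (j == n - 1) break;
    if (depth[j + 1] <= dry) { dead = true; continue; }
    double F1 = step_flux(flux[j], depth[j], depth[j + 1], cf[j], cf[j + 1],
                          veg_on[j], veg_on[j + 1]);
    hs[j + 1] = hs_of(F1, depth[j + 1]);
  }
  return List::create(_["hs"] = hs, _["eps_break"] = eb, _["eps_fric"] = ef,
                      _["eps_veg"] = ev, _["flux"] = flux);
}
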