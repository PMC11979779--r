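// Numerical kernel: co-limited leaf photosynthesis, soil-plant hydraulics,
// two-segment diurnal (SDM-2) fitness integration, and the weekly/daily
// trait optimization.  All temperatures cross the R/C++ boundary in degC;
// conversion to K happens only inside the Arrhenius/peaked temperature
// response functions.  Water potentials in MPa, pressures in Pa, fluxes in
// mol m-2 s-1 unless noted.

#include <Rcpp.h>
#include <cmath>
#include <functional>
#include <vector>
#include <algorithm>

using namespace Rcpp;

static const double RGAS = 8.314;     // J K-1 mol-1
static const double KELVIN = 273.15;
static const double MOLMASS_C = 12.011;   // g mol-1
static const double MOLMASS_H2O = 18.015; // g mol-1

// ---------------------------------------------------------------------------
// parameter structs

struct PhotoP {
  double gamma_ref, EAg, EAJ, EDJ, Topt, thJ, alpha, aJ, Smin, dS, tau,
    gratio, Tref; // Topt, Tref in K; energies in J mol-1
};
struct HydP {
  double kmax, p50, b, fcrit, ths, thr, psia, lambda, rho, grav;
};
struct CostP { double Nr, Nu; };
struct StandP { double H, LAI, kext, m, zeta; };

struct Params {
  PhotoP ph; HydP hy; CostP co; StandP st; double Patm;
};

struct Opts {
  int panels, fp_maxit, nm_maxit, nstarts, grid_n, grid_g;
  double fp_tol, nm_tol, gs_min, gs_max, nmf_min, nmf_max;
  bool daily_refine, night_cost;
};

static double lget(const List& l, const char* nm) {
  return as<double>(l[nm]);
}

static PhotoP as_photo(const List& l) {
  PhotoP p;
  p.gamma_ref = lget(l, "gamma_star_ref"); p.EAg = lget(l, "e_a_gamma");
  p.EAJ = lget(l, "e_a_j"); p.EDJ = lget(l, "e_d_j"); p.Topt = lget(l, "t_opt");
  p.thJ = lget(l, "theta_j"); p.alpha = lget(l, "alpha_season");
  p.aJ = lget(l, "a_jmax"); p.Smin = lget(l, "s_min"); p.dS = lget(l, "delta_s");
  p.tau = lget(l, "tau"); p.gratio = lget(l, "g_ratio"); p.Tref = lget(l, "t_ref");
  return p;
}
static HydP as_hyd(const List& l) {
  HydP h;
  h.kmax = lget(l, "k_sc_max"); h.p50 = lget(l, "psi50_sc"); h.b = lget(l, "b_sc");
  h.fcrit = lget(l, "f_crit"); h.ths = lget(l, "theta_s"); h.thr = lget(l, "theta_r");
  h.psia = lget(l, "psi_a"); h.lambda = lget(l, "lambda_pore");
  h.rho = lget(l, "rho_w"); h.grav = lget(l, "g_grav");
  return h;
}
static CostP as_cost(const List& l) {
  CostP c; c.Nr = lget(l, "n_r"); c.Nu = lget(l, "n_u"); return c;
}
static StandP as_stand(const List& l) {
  StandP s;
  s.H = lget(l, "height"); s.LAI = lget(l, "lai"); s.kext = lget(l, "k_ext");
  s.m = lget(l, "m_leaf"); s.zeta = lget(l, "zeta");
  return s;
}
static Params as_params(const List& l) {
  Params p;
  p.ph = as_photo(l["photo"]); p.hy = as_hyd(l["hydraulics"]);
  p.co = as_cost(l["cost"]); p.st = as_stand(l["stand"]);
  p.Patm = lget(l, "p_atm");
  return p;
}
static Opts as_opts(const List& l) {
  Opts o;
  o.panels = as<int>(l["panels"]); o.fp_tol = lget(l, "fp_tol");
  o.fp_maxit = as<int>(l["fp_maxit"]); o.nm_tol = lget(l, "nm_tol");
  o.nm_maxit = as<int>(l["nm_maxit"]); o.nstarts = as<int>(l["nstarts"]);
  o.grid_n = as<int>(l["grid_n"]); o.grid_g = as<int>(l["grid_g"]);
  o.gs_min = lget(l, "gs_min"); o.gs_max = lget(l, "gs_max");
  o.nmf_min = lget(l, "nmf_min"); o.nmf_max = lget(l, "nmf_max");
  o.daily_refine = as<bool>(l["daily_refine"]);
  o.night_cost = as<bool>(l["night_cost"]);
  return o;
}

// ---------------------------------------------------------------------------
// photosynthesis primitives

static double gamma_star_1(double TaC, const PhotoP& p) {
  double T = TaC + KELVIN;
  return p.gamma_ref * std::exp(p.EAg * (T - p.Tref) / (T * RGAS * p.Tref));
}

// peaked temperature response of Jmax; 1 at T = Topt
static double fjmax_1(double TaC, const PhotoP& p) {
  double T = TaC + KELVIN;
  double num = p.EDJ * std::exp(p.EAJ * (T - p.Topt) / (T * RGAS * p.Topt));
  double den = p.EDJ - p.EAJ * (1.0 - std::exp(p.EDJ * (T - p.Topt) / (T * RGAS * p.Topt)));
  if (den <= 0.0) return NA_REAL; // invalid-parameter region
  return num / den;
}

// smaller root of thJ*J^2 - (aI + Jm)*J + aI*Jm = 0 (non-rectangular hyperbola)
static double etrans_core(double alphaI, double Jm, double thJ) {
  if (alphaI <= 0.0 || Jm <= 0.0) return 0.0;
  double s = alphaI + Jm;
  double disc = s * s - 4.0 * thJ * alphaI * Jm;
  if (disc < 0.0) disc = 0.0; // roundoff; disc >= (aI-Jm)^2 + 4(1-th)aIJm >= 0
  return 2.0 * alphaI * Jm / (s + std::sqrt(disc));
}

// greater root of ci^2 + B*ci - C = 0 (supply/demand balance)
static double ci_root(double g, double ca, double gam, double J, double Patm) {
  if (J <= 0.0) return ca;
  double q = J * Patm / (4.0 * g);
  double B = q + 2.0 * gam - ca;
  double C = q * gam + 2.0 * ca * gam; // >= 0
  double disc = std::sqrt(B * B + 4.0 * C);
  double ci = (B > 0.0) ? 2.0 * C / (B + disc) : 0.5 * (-B + disc);
  return ci;
}

struct Assim { double A, ci, J, Jmax; };

static Assim assim_1(double gs, double Iinc, double TaC, double ca,
                     double Nmf, double Xt, const PhotoP& p, double Patm) {
  Assim out;
  double fj = fjmax_1(TaC, p);
  double Jms = p.aJ * Nmf * fj;          // J_max,season(T, N)
  out.Jmax = Xt * Jms;                    // instantaneous Jmax (X_t scaled)
  double Jcore = etrans_core(p.alpha * Iinc, Jms, p.thJ);
  out.J = Xt * Jcore;
  if (out.J <= 0.0 || gs <= 0.0) { out.A = 0.0; out.ci = ca; return out; }
  double gam = gamma_star_1(TaC, p);
  double g = p.gratio * gs;
  out.ci = ci_root(g, ca, gam, out.J, Patm);
  out.A = g / Patm * (ca - out.ci);
  if (out.A < 0.0 && ca >= gam) out.A = 0.0; // roundoff guard
  return out;
}

// ---------------------------------------------------------------------------
// hydraulics primitives

static double soil_psi_1(double theta, const HydP& h) {
  double Se = (theta - h.thr) / (h.ths - h.thr);
  if (Se <= 0.0 || theta > h.ths) return NA_REAL;
  return h.psia * std::pow(Se, -1.0 / h.lambda);
}

static double vuln_1(double psi, const HydP& h) {
  double r = psi / h.p50; // both negative -> ratio >= 0
  if (r <= 0.0) return 1.0;
  return std::pow(0.5, std::pow(r, h.b));
}

// Simpson 1/3 integral of P(psi) over [a, b], n panels (even)
static double simpson_intP(double a, double b, const HydP& h, int n) {
  if (a == b) return 0.0;
  if (n % 2 == 1) ++n;
  double hstep = (b - a) / n;
  double s = vuln_1(a, h) + vuln_1(b, h);
  for (int i = 1; i < n; ++i)
    s += (i % 2 == 1 ? 4.0 : 2.0) * vuln_1(a + i * hstep, h);
  return s * hstep / 3.0;
}

struct CanopyState {
  double psi_c, psi_pd, ksc, E; bool ok; int iters;
};

// coupled Darcy / integral-mean-conductance solve by damped fixed point
static CanopyState canopy_state_1(double gs, double VPD, double theta, double H,
                                  const HydP& h, double Patm,
                                  int panels, double tol, int maxit) {
  CanopyState st; st.ok = true; st.iters = 0;
  double psis = soil_psi_1(theta, h);
  if (!std::isfinite(psis)) { st.psi_c = st.psi_pd = st.ksc = st.E = NA_REAL; st.ok = false; return st; }
  double pd = psis - H * h.rho * h.grav * 1e-6;
  st.psi_pd = pd;
  double E = 1.6 * gs * VPD / Patm;
  st.E = E;
  if (E <= 0.0) { st.psi_c = pd; st.ksc = h.kmax * vuln_1(pd, h); return st; }
  double floorPsi = 10.0 * h.p50; // P ~ 0 here; beyond = runaway embolism
  double k = h.kmax * vuln_1(pd, h);
  double prev_delta = 0.0, psi_c = pd;
  bool converged = false;
  for (int it = 1; it <= maxit; ++it) {
    st.iters = it;
    psi_c = pd - E / k;
    if (psi_c < floorPsi || k <= h.kmax * 1e-12) { st.ok = false; break; }
    double knew = h.kmax * simpson_intP(psi_c, pd, h, panels) / (pd - psi_c);
    double delta = knew - k;
    if (std::fabs(delta) <= tol * std::fabs(k)) { k = knew; converged = true; break; }
    if (prev_delta != 0.0 && delta * prev_delta < 0.0)
      knew = 0.5 * (knew + k); // damp oscillation
    prev_delta = delta;
    k = knew;
  }
  if (!converged && st.ok) st.ok = false;
  st.ksc = k;
  st.psi_c = pd - E / k;
  if (!st.ok) { st.psi_c = NA_REAL; st.ksc = NA_REAL; }
  return st;
}

// stomatal conductance at which P(psi_c) = f_crit (closed-form via the
// supply integral; consistent with the fixed-point discretization)
static double crit_gs_1(double VPD, double theta, double H, const HydP& h,
                        double Patm, int panels, double gs_max) {
  double psis = soil_psi_1(theta, h);
  if (!std::isfinite(psis)) return NA_REAL;
  double pd = psis - H * h.rho * h.grav * 1e-6;
  if (vuln_1(pd, h) <= h.fcrit) return NA_REAL; // already beyond critical
  double psi_crit = h.p50 * std::pow(std::log(h.fcrit) / std::log(0.5), 1.0 / h.b);
  double Ecrit = h.kmax * simpson_intP(psi_crit, pd, h, panels);
  if (VPD <= 0.0) return gs_max;
  double gs = Ecrit * Patm / (1.6 * VPD);
  return std::min(gs, gs_max);
}

// ---------------------------------------------------------------------------
// diurnal drivers (SDM-2): day-level forcing -> instantaneous values

struct Env { double I0, Tmin, Tmean, Tmax, VPD, ca, theta, dtg; };

static Env env_from_row(const NumericMatrix& w, int i) {
  Env e;
  e.I0 = w(i, 0); e.Tmin = w(i, 1); e.Tmean = w(i, 2); e.Tmax = w(i, 3);
  e.VPD = w(i, 4); e.ca = w(i, 5); e.theta = w(i, 6); e.dtg = w(i, 7);
  return e;
}

static double esat_tetens(double TC) {
  return 610.78 * std::exp(17.27 * TC / (TC + 237.3));
}

struct Inst { double I, T, VPD; };

// t in seconds from sunrise; D = daylight length in seconds
static Inst diurnal_1(const Env& e, double t) {
  Inst s;
  double D = e.dtg * 3600.0;
  s.I = M_PI * e.I0 / (2.0 * D) * std::sin(M_PI * t / D); // mol m-2 s-1
  double A = 0.5 * (e.Tmax - e.Tmin);
  double T = e.Tmean + A * std::cos(M_PI * (t - 0.75 * D) / D); // peak mid-afternoon
  if (T < e.Tmin) T = e.Tmin;
  if (T > e.Tmax) T = e.Tmax;
  s.T = T;
  double ea = esat_tetens(e.Tmean) - e.VPD; // daily actual vapor pressure
  if (ea < 0.0) ea = 0.0;
  double vpd = esat_tetens(T) - ea;
  s.VPD = vpd > 0.0 ? vpd : 0.0;
  return s;
}

struct Seg { double I, T, VPD, dur; }; // dur in seconds

static void segments_2(const Env& e, Seg seg[2]) {
  double D = e.dtg * 3600.0;
  double tm[2] = { 0.25 * D, 0.75 * D };
  for (int i = 0; i < 2; ++i) {
    Inst s = diurnal_1(e, tm[i]);
    seg[i].I = s.I; seg[i].T = s.T; seg[i].VPD = s.VPD; seg[i].dur = 0.5 * D;
  }
}

// ---------------------------------------------------------------------------
// fitness proxy

struct SegFit { double G, A, ksc, psi_c, kcost; bool ok; };

static SegFit seg_fitness(double gs, double Nmf, const Seg& s, double ca,
                          double theta, double Xt, const Params& P, const Opts& O) {
  SegFit f;
  double Iinc = P.st.kext * s.I / (1.0 - P.st.m); // top-leaf incident irradiance
  Assim a = assim_1(gs, Iinc, s.T, ca, Nmf, Xt, P.ph, P.Patm);
  CanopyState cs = canopy_state_1(gs, s.VPD, theta, P.st.H, P.hy, P.Patm,
                                  O.panels, O.fp_tol, O.fp_maxit);
  f.ok = cs.ok;
  f.A = a.A; f.ksc = cs.ksc; f.psi_c = cs.psi_c;
  if (!cs.ok) { f.G = -1e6; f.kcost = NA_REAL; return f; } // hydraulic failure
  double kcrit = P.hy.fcrit * P.hy.kmax;
  f.kcost = (cs.ksc - kcrit) / (P.hy.kmax - kcrit);
  f.G = a.A * f.kcost - (P.co.Nr + P.co.Nu) * a.Jmax;
  return f;
}

// daily integral of G by the two-segment scheme; mol C m-2 day-1
static double daily_fitness_1(double gam, double gpm, double Nmf, const Env& e,
                              double Xt, const Params& P, const Opts& O, bool* okp) {
  Seg seg[2];
  segments_2(e, seg);
  double gs[2] = { gam, gpm };
  double tot = 0.0; bool ok = true;
  for (int i = 0; i < 2; ++i) {
    SegFit f = seg_fitness(gs[i], Nmf, seg[i], e.ca, e.theta, Xt, P, O);
    if (!f.ok) ok = false;
    tot += f.G * seg[i].dur;
  }
  if (O.night_cost) {
    double fj = fjmax_1(e.Tmean, P.ph);
    double Jmax_night = Xt * P.ph.aJ * Nmf * fj;
    tot -= (P.co.Nr + P.co.Nu) * Jmax_night * (86400.0 - e.dtg * 3600.0);
  }
  if (okp) *okp = ok;
  return tot;
}

// weekly objective: sum of daily fitness on the week-average day with each
// day's own acclimation factor.  The canopy hydraulic states depend only on
// the conductances (the average-day environment is shared), so the two
// solves are hoisted out of the day loop; results are identical to summing
// daily_fitness_1 over the block.
static double weekly_obj(double Nmf, double gam, double gpm, const Env& avg,
                         const std::vector<double>& Xts, const Params& P, const Opts& O) {
  size_t nd = Xts.size();
  Seg seg[2];
  segments_2(avg, seg);
  double gs[2] = { gam, gpm };
  double kc[2];
  double kcrit = P.hy.fcrit * P.hy.kmax;
  for (int i = 0; i < 2; ++i) {
    CanopyState cs = canopy_state_1(gs[i], seg[i].VPD, avg.theta, P.st.H, P.hy,
                                    P.Patm, O.panels, O.fp_tol, O.fp_maxit);
    if (!cs.ok) return -1e6 * (double)nd;
    kc[i] = (cs.ksc - kcrit) / (P.hy.kmax - kcrit);
  }
  double Iinc[2] = { P.st.kext * seg[0].I / (1.0 - P.st.m),
                     P.st.kext * seg[1].I / (1.0 - P.st.m) };
  double tot = 0.0;
  for (size_t d = 0; d < nd; ++d) {
    for (int i = 0; i < 2; ++i) {
      Assim a = assim_1(gs[i], Iinc[i], seg[i].T, avg.ca, Nmf, Xts[d], P.ph, P.Patm);
      tot += (a.A * kc[i] - (P.co.Nr + P.co.Nu) * a.Jmax) * seg[i].dur;
    }
    if (O.night_cost) {
      double fj = fjmax_1(avg.Tmean, P.ph);
      tot -= (P.co.Nr + P.co.Nu) * Xts[d] * P.ph.aJ * Nmf * fj *
        (86400.0 - avg.dtg * 3600.0);
    }
  }
  return tot;
}

// ---------------------------------------------------------------------------
// bounded Nelder-Mead (projection onto the box), maximization

typedef std::function<double(const std::vector<double>&)> ObjFn;

static void clampv(std::vector<double>& x, const std::vector<double>& lo,
                   const std::vector<double>& hi) {
  for (size_t i = 0; i < x.size(); ++i)
    x[i] = std::min(std::max(x[i], lo[i]), hi[i]);
}

static std::vector<double> nm_maximize(ObjFn f, std::vector<double> x0,
                                       const std::vector<double>& lo,
                                       const std::vector<double>& hi,
                                       double tol, int maxit, double* fbest) {
  const int n = (int)x0.size();
  clampv(x0, lo, hi);
  std::vector<std::vector<double> > sx(n + 1, x0);
  std::vector<double> fv(n + 1);
  for (int i = 0; i < n; ++i) {
    double step = 0.1 * (hi[i] - lo[i]);
    sx[i + 1][i] += (sx[i + 1][i] + step <= hi[i]) ? step : -step;
    clampv(sx[i + 1], lo, hi);
  }
  for (int i = 0; i <= n; ++i) fv[i] = f(sx[i]);
  int it = 0;
  while (it++ < maxit) {
    // order descending (maximization: best first)
    std::vector<int> idx(n + 1);
    for (int i = 0; i <= n; ++i) idx[i] = i;
    std::sort(idx.begin(), idx.end(), [&](int a, int b) { return fv[a] > fv[b]; });
    std::vector<std::vector<double> > sx2(n + 1);
    std::vector<double> fv2(n + 1);
    for (int i = 0; i <= n; ++i) { sx2[i] = sx[idx[i]]; fv2[i] = fv[idx[i]]; }
    sx = sx2; fv = fv2;
    double scale = 0.0;
    for (int i = 0; i < n; ++i)
      scale = std::max(scale, std::fabs(sx[0][i] - sx[n][i]) / std::max(hi[i] - lo[i], 1e-300));
    if (std::fabs(fv[0] - fv[n]) <= tol * (std::fabs(fv[0]) + tol) && scale < 1e-6) break;
    std::vector<double> cen(n, 0.0);
    for (int i = 0; i < n; ++i) {
      for (int j = 0; j < n; ++j) cen[j] += sx[i][j];
    }
    for (int j = 0; j < n; ++j) cen[j] /= n;
    auto propose = [&](double coef) {
      std::vector<double> p(n);
      for (int j = 0; j < n; ++j) p[j] = cen[j] + coef * (cen[j] - sx[n][j]);
      clampv(p, lo, hi);
      return p;
    };
    std::vector<double> xr = propose(1.0);
    double fr = f(xr);
    if (fr > fv[0]) {
      std::vector<double> xe = propose(2.0);
      double fe = f(xe);
      if (fe > fr) { sx[n] = xe; fv[n] = fe; } else { sx[n] = xr; fv[n] = fr; }
    } else if (fr > fv[n - 1]) {
      sx[n] = xr; fv[n] = fr;
    } else {
      std::vector<double> xc = propose(-0.5);
      double fc = f(xc);
      if (fc > fv[n]) { sx[n] = xc; fv[n] = fc; }
      else { // shrink toward best
        for (int i = 1; i <= n; ++i) {
          for (int j = 0; j < n; ++j) sx[i][j] = 0.5 * (sx[i][j] + sx[0][j]);
          clampv(sx[i], lo, hi);
          fv[i] = f(sx[i]);
        }
      }
    }
  }
  int best = 0;
  for (int i = 1; i <= n; ++i) if (fv[i] > fv[best]) best = i;
  if (fbest) *fbest = fv[best];
  return sx[best];
}

// ---------------------------------------------------------------------------
// weekly optimization (two-step routine)

struct WeekEnv {
  std::vector<Env> days;
  Env avg;
  std::vector<double> Xts;
};

static Env average_env(const std::vector<Env>& days) {
  Env a; a.I0 = a.Tmin = a.Tmean = a.Tmax = a.VPD = a.ca = a.theta = a.dtg = 0.0;
  for (const Env& e : days) {
    a.I0 += e.I0; a.Tmin += e.Tmin; a.Tmean += e.Tmean; a.Tmax += e.Tmax;
    a.VPD += e.VPD; a.ca += e.ca; a.theta += e.theta; a.dtg += e.dtg;
  }
  double n = (double)days.size();
  a.I0 /= n; a.Tmin /= n; a.Tmean /= n; a.Tmax /= n;
  a.VPD /= n; a.ca /= n; a.theta /= n; a.dtg /= n;
  return a;
}

// per-segment critical gs bounds for one day; returns false if even closed
// stomata violate the cavitation threshold
static bool seg_gs_bounds(const Env& e, const Params& P, const Opts& O,
                          double gcrit[2]) {
  Seg seg[2];
  segments_2(e, seg);
  bool ok = true;
  for (int i = 0; i < 2; ++i) {
    double gc = crit_gs_1(seg[i].VPD, e.theta, P.st.H, P.hy, P.Patm, O.panels, O.gs_max);
    if (!std::isfinite(gc) || gc < O.gs_min) { gc = O.gs_min; ok = false; }
    gcrit[i] = gc;
  }
  return ok;
}

// factorized batch evaluation of the weekly objective on a (N, gs_am, gs_pm)
// grid: canopy states depend on gs only, assimilation on (N, gs); grouping
// the shared sub-computations makes large grids cheap while evaluating the
// exact same objective values
static void weekly_grid(const Env& avg, const std::vector<double>& Xts,
                        const Params& P, const Opts& O,
                        const std::vector<double>& Ns,
                        const std::vector<double>& gam,
                        const std::vector<double>& gpm,
                        std::vector<double>& out /* iN + nN*(ia + na*ip) */) {
  Seg seg[2];
  segments_2(avg, seg);
  size_t nN = Ns.size(), na = gam.size(), np = gpm.size(), nd = Xts.size();
  double kcrit = P.hy.fcrit * P.hy.kmax;
  // kcost per segment per gs value
  std::vector<double> kc_am(na), kc_pm(np);
  std::vector<bool> ok_am(na), ok_pm(np);
  for (size_t i = 0; i < na; ++i) {
    CanopyState cs = canopy_state_1(gam[i], seg[0].VPD, avg.theta, P.st.H, P.hy,
                                    P.Patm, O.panels, O.fp_tol, O.fp_maxit);
    ok_am[i] = cs.ok;
    kc_am[i] = cs.ok ? (cs.ksc - kcrit) / (P.hy.kmax - kcrit) : NA_REAL;
  }
  for (size_t i = 0; i < np; ++i) {
    CanopyState cs = canopy_state_1(gpm[i], seg[1].VPD, avg.theta, P.st.H, P.hy,
                                    P.Patm, O.panels, O.fp_tol, O.fp_maxit);
    ok_pm[i] = cs.ok;
    kc_pm[i] = cs.ok ? (cs.ksc - kcrit) / (P.hy.kmax - kcrit) : NA_REAL;
  }
  // G contribution per (day, segment, gs, N), summed over days on the fly
  // (avg day is shared; only Xt differs between days)
  std::vector<double> Gam(na * nN, 0.0), Gpm(np * nN, 0.0);
  double Iinc[2] = { P.st.kext * seg[0].I / (1.0 - P.st.m),
                     P.st.kext * seg[1].I / (1.0 - P.st.m) };
  for (size_t d = 0; d < nd; ++d) {
    double Xt = Xts[d];
    for (size_t iN = 0; iN < nN; ++iN) {
      for (size_t i = 0; i < na; ++i) {
        double G;
        if (!ok_am[i]) G = -1e6;
        else {
          Assim a = assim_1(gam[i], Iinc[0], seg[0].T, avg.ca, Ns[iN], Xt, P.ph, P.Patm);
          G = a.A * kc_am[i] - (P.co.Nr + P.co.Nu) * a.Jmax;
        }
        Gam[i * nN + iN] += G * seg[0].dur;
      }
      for (size_t i = 0; i < np; ++i) {
        double G;
        if (!ok_pm[i]) G = -1e6;
        else {
          Assim a = assim_1(gpm[i], Iinc[1], seg[1].T, avg.ca, Ns[iN], Xt, P.ph, P.Patm);
          G = a.A * kc_pm[i] - (P.co.Nr + P.co.Nu) * a.Jmax;
        }
        Gpm[i * nN + iN] += G * seg[1].dur;
      }
    }
  }
  double night = 0.0;
  out.assign(nN * na * np, 0.0);
  for (size_t ip = 0; ip < np; ++ip)
    for (size_t ia = 0; ia < na; ++ia)
      for (size_t iN = 0; iN < nN; ++iN)
        out[iN + nN * (ia + na * ip)] = Gam[ia * nN + iN] + Gpm[ip * nN + iN] + night;
  if (O.night_cost) {
    double fj = fjmax_1(avg.Tmean, P.ph);
    double Xsum = 0.0;
    for (double x : Xts) Xsum += x;
    double nsec = 86400.0 - avg.dtg * 3600.0;
    for (size_t iN = 0; iN < nN; ++iN) {
      double pen = (P.co.Nr + P.co.Nu) * P.ph.aJ * Ns[iN] * fj * Xsum * nsec;
      for (size_t ip = 0; ip < np; ++ip)
        for (size_t ia = 0; ia < na; ++ia)
          out[iN + nN * (ia + na * ip)] -= pen;
    }
  }
}

static std::vector<double> linspace(double a, double b, int n) {
  std::vector<double> v(n);
  if (n == 1) { v[0] = 0.5 * (a + b); return v; }
  for (int i = 0; i < n; ++i) v[i] = a + (b - a) * i / (n - 1.0);
  return v;
}

struct WeekSol {
  double Nmf, fitness;
  std::vector<double> gs_am, gs_pm;
  std::vector<int> flag; // 0 ok, 1 beyond-critical clamp
  double step1_am, step1_pm;
};

static WeekSol optimize_week_c(const std::vector<Env>& days,
                               const std::vector<double>& Xts,
                               const Params& P, const Opts& O) {
  WeekSol sol;
  size_t nd = days.size();
  Env avg = average_env(days);
  double gcrit_avg[2];
  bool avg_ok = seg_gs_bounds(avg, P, O, gcrit_avg);
  double Nlo = O.nmf_min, Nhi = O.nmf_max;
  if (!avg_ok) {
    // even closed stomata beyond threshold on the average day: boundary solution
    sol.Nmf = Nlo; sol.step1_am = sol.step1_pm = O.gs_min;
  } else {
    std::vector<double> Ns = linspace(Nlo, Nhi, O.grid_n);
    std::vector<double> ga = linspace(O.gs_min, gcrit_avg[0], O.grid_g);
    std::vector<double> gp = linspace(O.gs_min, gcrit_avg[1], O.grid_g);
    std::vector<double> grid;
    weekly_grid(avg, Xts, P, O, Ns, ga, gp, grid);
    // top nstarts cells, then Nelder-Mead polish on the true objective
    std::vector<size_t> order(grid.size());
    for (size_t i = 0; i < order.size(); ++i) order[i] = i;
    std::partial_sort(order.begin(),
                      order.begin() + std::min((size_t)O.nstarts, order.size()),
                      order.end(),
                      [&](size_t a, size_t b) { return grid[a] > grid[b]; });
    std::vector<double> lo = { Nlo, O.gs_min, O.gs_min };
    std::vector<double> hi = { Nhi, gcrit_avg[0], gcrit_avg[1] };
    ObjFn f = [&](const std::vector<double>& x) {
      return weekly_obj(x[0], x[1], x[2], avg, Xts, P, O);
    };
    double bestf = -1e300;
    std::vector<double> bestx = { 0.5 * (Nlo + Nhi), 0.5 * (O.gs_min + gcrit_avg[0]),
                                  0.5 * (O.gs_min + gcrit_avg[1]) };
    int ns = std::min((size_t)O.nstarts, order.size());
    size_t nN = Ns.size(), na = ga.size();
    for (int s = 0; s < ns; ++s) {
      size_t id = order[s];
      size_t iN = id % nN, ia = (id / nN) % na, ip = id / (nN * na);
      std::vector<double> x0 = { Ns[iN], ga[ia], gp[ip] };
      double fb;
      std::vector<double> xb = nm_maximize(f, x0, lo, hi, O.nm_tol, O.nm_maxit, &fb);
      if (fb > bestf) { bestf = fb; bestx = xb; }
    }
    sol.Nmf = bestx[0]; sol.step1_am = bestx[1]; sol.step1_pm = bestx[2];
  }
  // step 2: per-day fine-tuning of the gs pair at fixed Nmf
  sol.gs_am.resize(nd); sol.gs_pm.resize(nd); sol.flag.assign(nd, 0);
  sol.fitness = 0.0;
  for (size_t d = 0; d < nd; ++d) {
    double gc[2];
    bool dok = seg_gs_bounds(days[d], P, O, gc);
    if (!dok) {
      sol.gs_am[d] = O.gs_min; sol.gs_pm[d] = O.gs_min; sol.flag[d] = 1;
    } else if (!O.daily_refine || !avg_ok) {
      sol.gs_am[d] = std::min(std::max(sol.step1_am, O.gs_min), gc[0]);
      sol.gs_pm[d] = std::min(std::max(sol.step1_pm, O.gs_min), gc[1]);
    } else {
      std::vector<double> lo2 = { O.gs_min, O.gs_min };
      std::vector<double> hi2 = { gc[0], gc[1] };
      const Env& e = days[d];
      double Xt = Xts[d], Nmf = sol.Nmf;
      ObjFn fd = [&](const std::vector<double>& x) {
        return daily_fitness_1(x[0], x[1], Nmf, e, Xt, P, O, nullptr);
      };
      std::vector<double> x0 = { sol.step1_am, sol.step1_pm };
      double fb;
      std::vector<double> xb = nm_maximize(fd, x0, lo2, hi2, O.nm_tol, O.nm_maxit, &fb);
      sol.gs_am[d] = xb[0]; sol.gs_pm[d] = xb[1];
    }
    sol.fitness += daily_fitness_1(sol.gs_am[d], sol.gs_pm[d], sol.Nmf,
                                   days[d], Xts[d], P, O, nullptr);
  }
  return sol;
}

// ---------------------------------------------------------------------------
// daily canopy fluxes (big-leaf upscaling)

struct DayFlux { double gpp_c, e_c, psi_min, kcost_min; bool ok; };

static DayFlux day_fluxes_1(double gam, double gpm, double Nmf, const Env& e,
                            double Xt, const Params& P, const Opts& O) {
  DayFlux out; out.ok = true;
  Seg seg[2];
  segments_2(e, seg);
  double lam = (P.st.kext > 0.0)
    ? (1.0 - std::exp(-P.st.kext * P.st.LAI)) / P.st.kext : P.st.LAI;
  double gs[2] = { gam, gpm };
  double gpp = 0.0, ec = 0.0, psimin = 0.0, kcmin = 1.0;
  for (int i = 0; i < 2; ++i) {
    SegFit f = seg_fitness(gs[i], Nmf, seg[i], e.ca, e.theta, Xt, P, O);
    if (!f.ok) { out.ok = false; continue; }
    gpp += lam * f.A * seg[i].dur;                       // mol C m-2 ground
    ec += 1.6 * gs[i] * lam * seg[i].VPD / P.Patm * seg[i].dur; // mol H2O m-2
    if (f.psi_c < psimin) psimin = f.psi_c;
    if (f.kcost < kcmin) kcmin = f.kcost;
  }
  out.gpp_c = gpp * MOLMASS_C;           // g C m-2 ground day-1
  out.e_c = ec * MOLMASS_H2O * 1e-3;     // kg m-2 = mm day-1
  out.psi_min = psimin; out.kcost_min = kcmin;
  return out;
}

// ---------------------------------------------------------------------------
// exported wrappers

// [[Rcpp::export]]
NumericVector cpp_gamma_star(NumericVector temp, List photo) {
  PhotoP p = as_photo(photo);
  NumericVector out(temp.size());
  for (int i = 0; i < temp.size(); ++i) out[i] = gamma_star_1(temp[i], p);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_f_jmax_temp(NumericVector temp, List photo) {
  PhotoP p = as_photo(photo);
  NumericVector out(temp.size());
  for (int i = 0; i < temp.size(); ++i) out[i] = fjmax_1(temp[i], p);
  return out;
}

// [[Rcpp::export]]
List cpp_acclimation(NumericVector tmean, double s0, List photo) {
  PhotoP p = as_photo(photo);
  int n = tmean.size();
  NumericVector S(n), X(n);
  double s = s0;
  for (int i = 0; i < n; ++i) {
    s = (1.0 - 1.0 / p.tau) * s + tmean[i] / p.tau;
    S[i] = s;
    double x = (s - p.Smin) / p.dS;
    X[i] = x <= 0.0 ? 0.0 : (x >= 1.0 ? 1.0 : x);
  }
  return List::create(_["s_t"] = S, _["x_t"] = X);
}

// [[Rcpp::export]]
NumericVector cpp_electron_transport(NumericVector i_inc, NumericVector jmax_season,
                                     NumericVector x_t, List photo) {
  PhotoP p = as_photo(photo);
  int n = std::max({ i_inc.size(), jmax_season.size(), x_t.size() });
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double aI = p.alpha * i_inc[i % i_inc.size()];
    out[i] = x_t[i % x_t.size()] * etrans_core(aI, jmax_season[i % jmax_season.size()], p.thJ);
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_solve_ci(NumericVector gs, NumericVector ca, NumericVector gamma,
                           NumericVector j, List photo, double p_atm) {
  PhotoP p = as_photo(photo);
  int n = std::max({ gs.size(), ca.size(), gamma.size(), j.size() });
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = ci_root(p.gratio * gs[i % gs.size()], ca[i % ca.size()],
                     gamma[i % gamma.size()], j[i % j.size()], p_atm);
  return out;
}

// [[Rcpp::export]]
List cpp_assimilation(NumericVector gs, NumericVector i_inc, NumericVector temp,
                      NumericVector ca, NumericVector n_mf, NumericVector x_t,
                      List photo, double p_atm) {
  PhotoP p = as_photo(photo);
  int n = std::max({ gs.size(), i_inc.size(), temp.size(), ca.size(),
                     n_mf.size(), x_t.size() });
  NumericVector A(n), ci(n), J(n), Jm(n);
  for (int i = 0; i < n; ++i) {
    Assim a = assim_1(gs[i % gs.size()], i_inc[i % i_inc.size()],
                      temp[i % temp.size()], ca[i % ca.size()],
                      n_mf[i % n_mf.size()], x_t[i % x_t.size()], p, p_atm);
    A[i] = a.A; ci[i] = a.ci; J[i] = a.J; Jm[i] = a.Jmax;
  }
  return List::create(_["a"] = A, _["ci"] = ci, _["j"] = J, _["jmax"] = Jm);
}

// [[Rcpp::export]]
NumericVector cpp_soil_water_potential(NumericVector theta, List hyd) {
  HydP h = as_hyd(hyd);
  NumericVector out(theta.size());
  for (int i = 0; i < theta.size(); ++i) out[i] = soil_psi_1(theta[i], h);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_vulnerability(NumericVector psi, List hyd) {
  HydP h = as_hyd(hyd);
  NumericVector out(psi.size());
  for (int i = 0; i < psi.size(); ++i) out[i] = vuln_1(psi[i], h);
  return out;
}

// [[Rcpp::export]]
List cpp_canopy_state(NumericVector gs, NumericVector vpd, NumericVector theta,
                      double height, List hyd, double p_atm,
                      int panels, double tol, int maxit) {
  HydP h = as_hyd(hyd);
  int n = std::max({ gs.size(), vpd.size(), theta.size() });
  NumericVector psic(n), psipd(n), ksc(n), E(n);
  LogicalVector ok(n);
  IntegerVector iters(n);
  for (int i = 0; i < n; ++i) {
    CanopyState st = canopy_state_1(gs[i % gs.size()], vpd[i % vpd.size()],
                                    theta[i % theta.size()], height, h, p_atm,
                                    panels, tol, maxit);
    psic[i] = st.psi_c; psipd[i] = st.psi_pd; ksc[i] = st.ksc; E[i] = st.E;
    ok[i] = st.ok; iters[i] = st.iters;
  }
  return List::create(_["psi_c"] = psic, _["psi_c_pd"] = psipd, _["k_sc"] = ksc,
                      _["e_leaf"] = E, _["converged"] = ok, _["iterations"] = iters);
}

// [[Rcpp::export]]
NumericVector cpp_critical_gs(NumericVector vpd, NumericVector theta, double height,
                              List hyd, double p_atm, int panels, double gs_max) {
  HydP h = as_hyd(hyd);
  int n = std::max(vpd.size(), theta.size());
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = crit_gs_1(vpd[i % vpd.size()], theta[i % theta.size()], height,
                       h, p_atm, panels, gs_max);
  return out;
}

// [[Rcpp::export]]
List cpp_diurnal(List day, NumericVector t_hours) {
  Env e;
  e.I0 = lget(day, "i0"); e.Tmin = lget(day, "t_min"); e.Tmean = lget(day, "t_mean");
  e.Tmax = lget(day, "t_max"); e.VPD = lget(day, "vpd"); e.ca = lget(day, "ca");
  e.theta = lget(day, "theta"); e.dtg = lget(day, "dt_g");
  int n = t_hours.size();
  NumericVector I(n), T(n), V(n);
  for (int i = 0; i < n; ++i) {
    Inst s = diurnal_1(e, t_hours[i] * 3600.0);
    I[i] = s.I; T[i] = s.T; V[i] = s.VPD;
  }
  return List::create(_["i"] = I, _["temp"] = T, _["vpd"] = V);
}

static std::vector<Env> envs_from_matrix(const NumericMatrix& w) {
  std::vector<Env> v(w.nrow());
  for (int i = 0; i < w.nrow(); ++i) v[i] = env_from_row(w, i);
  return v;
}

// [[Rcpp::export]]
double cpp_daily_fitness(double gs_am, double gs_pm, double n_mf,
                         NumericMatrix day, double x_t, List params, List opts) {
  Params P = as_params(params);
  Opts O = as_opts(opts);
  Env e = env_from_row(day, 0);
  return daily_fitness_1(gs_am, gs_pm, n_mf, e, x_t, P, O, nullptr);
}

// [[Rcpp::export]]
double cpp_weekly_fitness(double n_mf, double gs_am, double gs_pm,
                          NumericMatrix days, NumericVector x_t,
                          List params, List opts) {
  Params P = as_params(params);
  Opts O = as_opts(opts);
  std::vector<Env> envs = envs_from_matrix(days);
  Env avg = average_env(envs);
  std::vector<double> X(x_t.begin(), x_t.end());
  return weekly_obj(n_mf, gs_am, gs_pm, avg, X, P, O);
}

// [[Rcpp::export]]
NumericVector cpp_weekly_fitness_grid(NumericVector n_mf, NumericVector gs_am,
                                      NumericVector gs_pm, NumericMatrix days,
                                      NumericVector x_t, List params, List opts) {
  Params P = as_params(params);
  Opts O = as_opts(opts);
  std::vector<Env> envs = envs_from_matrix(days);
  Env avg = average_env(envs);
  std::vector<double> X(x_t.begin(), x_t.end());
  std::vector<double> Ns(n_mf.begin(), n_mf.end());
  std::vector<double> ga(gs_am.begin(), gs_am.end());
  std::vector<double> gp(gs_pm.begin(), gs_pm.end());
  std::vector<double> out;
  weekly_grid(avg, X, P, O, Ns, ga, gp, out);
  NumericVector res(out.begin(), out.end());
  res.attr("dim") = IntegerVector::create((int)Ns.size(), (int)ga.size(), (int)gp.size());
  return res;
}

// [[Rcpp::export]]
List cpp_optimize_week(NumericMatrix days, NumericVector x_t, List params, List opts) {
  Params P = as_params(params);
  Opts O = as_opts(opts);
  std::vector<Env> envs = envs_from_matrix(days);
  std::vector<double> X(x_t.begin(), x_t.end());
  WeekSol s = optimize_week_c(envs, X, P, O);
  return List::create(
    _["n_mf"] = s.Nmf,
    _["gs_am"] = NumericVector(s.gs_am.begin(), s.gs_am.end()),
    _["gs_pm"] = NumericVector(s.gs_pm.begin(), s.gs_pm.end()),
    _["fitness"] = s.fitness,
    _["flag"] = IntegerVector(s.flag.begin(), s.flag.end()),
    _["step1_gs_am"] = s.step1_am, _["step1_gs_pm"] = s.step1_pm);
}

// [[Rcpp::export]]
List cpp_day_fluxes(double gs_am, double gs_pm, double n_mf, NumericMatrix day,
                    double x_t, List params, List opts) {
  Params P = as_params(params);
  Opts O = as_opts(opts);
  Env e = env_from_row(day, 0);
  DayFlux f = day_fluxes_1(gs_am, gs_pm, n_mf, e, x_t, P, O);
  return List::create(_["gpp_c"] = f.gpp_c, _["e_c"] = f.e_c,
                      _["psi_c_min"] = f.psi_min, _["k_cost_min"] = f.kcost_min,
                      _["ok"] = f.ok);
}

// full season: acclimation advance, week-block optimization, upscaling
// [[Rcpp::export]]
List cpp_run_season(NumericMatrix weather, List params, List opts, double s0) {
  Params P = as_params(params);
  Opts O = as_opts(opts);
  int n = weather.nrow();
  std::vector<Env> envs = envs_from_matrix(weather);
  // acclimation from daily mean temperature
  NumericVector S(n), X(n);
  double s = s0;
  for (int i = 0; i < n; ++i) {
    s = (1.0 - 1.0 / P.ph.tau) * s + envs[i].Tmean / P.ph.tau;
    S[i] = s;
    double x = (s - P.ph.Smin) / P.ph.dS;
    X[i] = x <= 0.0 ? 0.0 : (x >= 1.0 ? 1.0 : x);
  }
  NumericVector nmf(n), gam(n), gpm(n), gpp(n), ec(n), psim(n), kcm(n), fitw(n);
  IntegerVector flag(n), week(n);
  int wk = 0;
  for (int start = 0; start < n; start += 7) {
    ++wk;
    int len = std::min(7, n - start);
    std::vector<Env> days(envs.begin() + start, envs.begin() + start + len);
    std::vector<double> Xts(X.begin() + start, X.begin() + start + len);
    WeekSol sol = optimize_week_c(days, Xts, P, O);
    for (int d = 0; d < len; ++d) {
      int i = start + d;
      nmf[i] = sol.Nmf; gam[i] = sol.gs_am[d]; gpm[i] = sol.gs_pm[d];
      flag[i] = sol.flag[d]; week[i] = wk; fitw[i] = sol.fitness;
      DayFlux f = day_fluxes_1(sol.gs_am[d], sol.gs_pm[d], sol.Nmf, envs[i], X[i], P, O);
      gpp[i] = f.gpp_c; ec[i] = f.e_c; psim[i] = f.psi_min; kcm[i] = f.kcost_min;
      if (!f.ok && flag[i] == 0) flag[i] = 2;
    }
  }
  return List::create(
    _["week"] = week, _["s_t"] = S, _["x_t"] = X, _["n_mf"] = nmf,
    _["gs_am"] = gam, _["gs_pm"] = gpm, _["gpp_c"] = gpp, _["e_c"] = ec,
    _["psi_c_min"] = psim, _["k_cost_min"] = kcm,
    _["fitness_weekly"] = fitw, _["flag"] = flag);
}
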