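// Structural model mathematics and the Laplace marginal-likelihood engine.
//
// PK: one-compartment, first-order elimination, parallel zero-order
// (duration D2, fraction fz) and lagged first-order (rate KA, lag ALAG)
// absorption.  Solved analytically.
//
// PD: turnover (indirect response) model with one transit compartment,
//   dA3/dt = Kin * E(C(t)) - Ktr * A3
//   dA4/dt = Ktr * A3      - Kout * A4
// driven by the analytic PK concentration through a sigmoid Emax
// stimulation with a time-increasing EC50.  Integrated numerically:
// adaptive Dormand-Prince RK45 (user-facing) or fixed-step RK4 on a
// breakpoint-aligned grid (estimation; discretisation error smooth in
// the parameters, so finite-difference gradients stay clean).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double LOG2PI = 1.8378770664093454836;

// ---------------------------------------------------------------- PK ----

// dose in mass units (ug), v in L, returns pg/mL (1 ug/L = 1000 pg/mL).
static double conc_one(double t, double dose, double cl, double v,
                       double d2, double ka, double alag, double fz) {
  if (t <= 0.0) return 0.0;
  const double ke = cl / v;
  double a = 0.0;                       // central amount, ug
  const double r0 = fz * dose / d2;     // zero-order input rate
  if (t <= d2)
    a += r0 / ke * (1.0 - std::exp(-ke * t));
  else
    a += r0 / ke * (1.0 - std::exp(-ke * d2)) * std::exp(-ke * (t - d2));
  if (t > alag) {
    const double tau = t - alag;
    const double d1  = (1.0 - fz) * dose;
    if (std::fabs(ka - ke) < 1e-10 * ke)      // analytic ka -> ke limit
      a += d1 * ke * tau * std::exp(-ke * tau);
    else
      a += d1 * ka / (ka - ke) * (std::exp(-ke * tau) - std::exp(-ka * tau));
  }
  return 1000.0 * a / v;
}

// [[Rcpp::export]]
NumericVector cpp_pk_conc(NumericVector t, double dose, double cl, double v,
                          double d2, double ka, double alag, double fz) {
  NumericVector out(t.size());
  for (R_xlen_t i = 0; i < t.size(); ++i)
    out[i] = conc_one(t[i], dose, cl, v, d2, ka, alag, fz);
  return out;
}

// -------------------------------------------------------------- PD ------

struct PDModel {
  // pk (already realized per subject)
  double dose, cl, v, d2, ka, alag, fz;
  // pd
  double kin, ktr, kout, emax, ga, ca, cb, ecb;
  double const_conc;  // >= 0 overrides the PK forcing (test mode)

  double conc(double t) const {
    if (const_conc >= 0.0) return const_conc;
    return conc_one(t, dose, cl, v, d2, ka, alag, fz);
  }
  double ec50(double t) const {
    return ecb * (1.0 + ca * (1.0 - std::exp(-cb * t)));
  }
  double effect(double c, double t) const {
    if (c <= 0.0) return 1.0;
    const double cg = std::exp(ga * std::log(c));
    const double eg = std::exp(ga * std::log(ec50(t)));
    return 1.0 + emax * cg / (eg + cg);
  }
  void rhs(double t, const double y[2], double dy[2]) const {
    const double e = effect(conc(t), t);
    dy[0] = kin * e - ktr * y[0];
    dy[1] = ktr * y[0] - kout * y[1];
  }
};

// Dormand-Prince 5(4) coefficients
static const double DP_C[7] = {0.0, 1.0/5, 3.0/10, 4.0/5, 8.0/9, 1.0, 1.0};
static const double DP_A[7][6] = {
  {0,0,0,0,0,0},
  {1.0/5,0,0,0,0,0},
  {3.0/40, 9.0/40,0,0,0,0},
  {44.0/45, -56.0/15, 32.0/9,0,0,0},
  {19372.0/6561, -25360.0/2187, 64448.0/6561, -212.0/729,0,0},
  {9017.0/3168, -355.0/33, 46732.0/5247, 49.0/176, -5103.0/18656,0},
  {35.0/384, 0, 500.0/1113, 125.0/192, -2187.0/6784, 11.0/84}};
static const double DP_B5[7] = {35.0/384, 0, 500.0/1113, 125.0/192,
                                -2187.0/6784, 11.0/84, 0};
static const double DP_B4[7] = {5179.0/57600, 0, 7571.0/16695, 393.0/640,
                                -92097.0/339200, 187.0/2100, 1.0/40};

// integrate from t0 to t1 (no internal discontinuities), y modified in place
static bool rk45_segment(const PDModel& m, double t0, double t1, double y[2],
                         double rtol, double atol) {
  if (t1 <= t0) return true;
  double t = t0, h = std::min(1.0, t1 - t0);
  const double hmin = 1e-12 * std::max(1.0, t1);
  int nstep = 0;
  double k[7][2], ytmp[2];
  while (t < t1) {
    if (++nstep > 1000000) return false;
    if (t + h > t1) h = t1 - t;
    m.rhs(t, y, k[0]);
    for (int s = 1; s < 7; ++s) {
      for (int d = 0; d < 2; ++d) {
        double acc = 0.0;
        for (int j = 0; j < s; ++j) acc += DP_A[s][j] * k[j][d];
        ytmp[d] = y[d] + h * acc;
      }
      m.rhs(t + DP_C[s] * h, ytmp, k[s]);
    }
    double y5[2], err = 0.0;
    for (int d = 0; d < 2; ++d) {
      double a5 = 0.0, a4 = 0.0;
      for (int s = 0; s < 7; ++s) { a5 += DP_B5[s]*k[s][d]; a4 += DP_B4[s]*k[s][d]; }
      y5[d] = y[d] + h * a5;
      const double sc = atol + rtol * std::max(std::fabs(y[d]), std::fabs(y5[d]));
      const double e  = h * (a5 - a4) / sc;
      err = std::max(err, std::fabs(e));
    }
    if (err <= 1.0) {
      t += h; y[0] = y5[0]; y[1] = y5[1];
    }
    double fac = (err > 0.0) ? 0.9 * std::pow(err, -0.2) : 5.0;
    fac = std::min(5.0, std::max(0.2, fac));
    h *= fac;
    if (h < hmin) return false;
  }
  return true;
}

// [[Rcpp::export]]
NumericVector cpp_pd_rk45(NumericVector times, double dose,
                          NumericVector pkpar,  // cl v d2 ka alag fz
                          NumericVector pdpar,  // base kout emax ga ca cb ecb mtt
                          double rtol, double atol, double const_conc) {
  PDModel m;
  m.dose = dose; m.cl = pkpar[0]; m.v = pkpar[1]; m.d2 = pkpar[2];
  m.ka = pkpar[3]; m.alag = pkpar[4]; m.fz = pkpar[5];
  const double base = pdpar[0], kout = pdpar[1], mtt = pdpar[7];
  m.kout = kout; m.emax = pdpar[2]; m.ga = pdpar[3]; m.ca = pdpar[4];
  m.cb = pdpar[5]; m.ecb = pdpar[6];
  m.ktr = 1.0 / mtt; m.kin = kout * base;
  m.const_conc = const_conc;

  const double tmax = times[times.size() - 1];
  // stop exactly at observation times and at the PK breakpoints (C' jumps)
  std::vector<double> stops(times.begin(), times.end());
  if (m.const_conc < 0.0) {
    if (m.d2 > 0 && m.d2 < tmax) stops.push_back(m.d2);
    if (m.alag > 0 && m.alag < tmax) stops.push_back(m.alag);
  }
  std::sort(stops.begin(), stops.end());
  stops.erase(std::unique(stops.begin(), stops.end()), stops.end());

  double y[2] = {m.kin / m.ktr, base};   // drug-free steady state
  NumericVector out(times.size());
  R_xlen_t oi = 0;
  double tcur = 0.0;
  // emit any t=0 observations
  while (oi < times.size() && times[oi] <= 0.0) out[oi++] = y[1];
  for (size_t s = 0; s < stops.size(); ++s) {
    const double tnext = stops[s];
    if (tnext <= tcur) continue;
    if (!rk45_segment(m, tcur, tnext, y, rtol, atol))
      stop("PD ODE integration failed between t=%f and t=%f "
           "(step size underflow or step limit)", tcur, tnext);
    tcur = tnext;
    while (oi < times.size() && times[oi] <= tcur + 1e-12) out[oi++] = y[1];
  }
  return out;
}

// ---------------------------------------------------- fixed-step grid ---

// Build the RK4 grid for one subject: step endpoints include every
// observation time; steps never exceed dt.  Stage times interleave the
// endpoints with midpoints: t0, m0, t1, m1, ..., tN  (2N+1 values).
// [[Rcpp::export]]
List cpp_pd_grid(NumericVector obs_times, double dt) {
  std::vector<double> knots;
  knots.push_back(0.0);
  double last = 0.0;
  for (R_xlen_t i = 0; i < obs_times.size(); ++i) {
    const double t = obs_times[i];
    if (t <= last + 1e-12) continue;
    const int n = (int)std::ceil((t - last) / dt - 1e-9);
    for (int j = 1; j <= n; ++j) knots.push_back(last + (t - last) * j / n);
    knots.back() = t;
    last = t;
  }
  const int N = (int)knots.size() - 1;
  NumericVector stage_t(2 * N + 1);
  for (int i = 0; i < N; ++i) {
    stage_t[2 * i]     = knots[i];
    stage_t[2 * i + 1] = 0.5 * (knots[i] + knots[i + 1]);
  }
  stage_t[2 * N] = knots[N];
  IntegerVector obs_idx(obs_times.size());   // knot index of each obs time
  int k = 0;
  for (R_xlen_t i = 0; i < obs_times.size(); ++i) {
    while (k <= N && std::fabs(knots[k] - obs_times[i]) > 1e-9) ++k;
    if (k > N) stop("internal: observation time not on grid");
    obs_idx[i] = k;
  }
  return List::create(_["stage_t"] = stage_t, _["obs_idx"] = obs_idx,
                      _["knots"] = NumericVector(knots.begin(), knots.end()));
}

// RK4 march over a precomputed grid with the stimulation E precomputed at
// every stage time.  Returns A4 at the observation knots.
static void rk4_march(const std::vector<double>& knots,
                      const std::vector<double>& ev,
                      double kin, double ktr, double kout, double base,
                      const IntegerVector& obs_idx, double* out) {
  const int N = (int)knots.size() - 1;
  double A3 = kin / ktr, A4 = base;
  // map knot index -> output slots (obs times are sorted, may repeat t=0)
  int oi = 0, nobs = obs_idx.size();
  while (oi < nobs && obs_idx[oi] == 0) out[oi++] = A4;
  for (int i = 0; i < N; ++i) {
    const double h = knots[i + 1] - knots[i];
    const double E1 = ev[2 * i], Em = ev[2 * i + 1], E2 = ev[2 * i + 2];
    double k13 = kin * E1 - ktr * A3,        k14 = ktr * A3 - kout * A4;
    double a3  = A3 + 0.5 * h * k13,         a4  = A4 + 0.5 * h * k14;
    double k23 = kin * Em - ktr * a3,        k24 = ktr * a3 - kout * a4;
    a3 = A3 + 0.5 * h * k23;                 a4 = A4 + 0.5 * h * k24;
    double k33 = kin * Em - ktr * a3,        k34 = ktr * a3 - kout * a4;
    a3 = A3 + h * k33;                       a4 = A4 + h * k34;
    double k43 = kin * E2 - ktr * a3,        k44 = ktr * a3 - kout * a4;
    A3 += h / 6.0 * (k13 + 2 * k23 + 2 * k33 + k43);
    A4 += h / 6.0 * (k14 + 2 * k24 + 2 * k34 + k44);
    while (oi < nobs && obs_idx[oi] == i + 1) out[oi++] = A4;
  }
}

// [[Rcpp::export]]
NumericVector cpp_pd_rk4(NumericVector obs_times, double dose,
                         NumericVector pkpar, NumericVector pdpar,
                         double dt, double const_conc) {
  List grid = cpp_pd_grid(obs_times, dt);
  NumericVector stage_t = grid["stage_t"];
  NumericVector knots_r = grid["knots"];
  IntegerVector obs_idx = grid["obs_idx"];
  PDModel m;
  m.dose = dose; m.cl = pkpar[0]; m.v = pkpar[1]; m.d2 = pkpar[2];
  m.ka = pkpar[3]; m.alag = pkpar[4]; m.fz = pkpar[5];
  const double base = pdpar[0], kout = pdpar[1], mtt = pdpar[7];
  m.kout = kout; m.emax = pdpar[2]; m.ga = pdpar[3]; m.ca = pdpar[4];
  m.cb = pdpar[5]; m.ecb = pdpar[6];
  m.ktr = 1.0 / mtt; m.kin = kout * base;
  m.const_conc = const_conc;
  const int S = stage_t.size();
  std::vector<double> ev(S);
  for (int s = 0; s < S; ++s) ev[s] = m.effect(m.conc(stage_t[s]), stage_t[s]);
  std::vector<double> knots(knots_r.begin(), knots_r.end());
  NumericVector out(obs_times.size());
  rk4_march(knots, ev, m.kin, m.ktr, m.kout, base, obs_idx, REAL(out));
  return out;
}

// ------------------------------------------------ Laplace OFV engine ----

// model kinds
enum { KIND_TOY = 0, KIND_PK = 1, KIND_PD = 2 };

struct SubjData {
  arma::vec t, y;
  double dose;
  // PD only: fixed individual PK parameters and precomputed grid
  double cl, v, d2, ka, alag, fz;
  std::vector<double> knots, stage_t, stage_c, stage_logc;
  IntegerVector obs_idx;
};

// prediction for one subject given typical values theta and eta
static arma::vec predict_subj(int kind, const SubjData& sd,
                              const arma::vec& theta,
                              const IntegerVector& eta_idx,
                              const arma::vec& eta, double dt_unused) {
  const int n = (int)sd.y.n_elem;
  arma::vec f(n);
  if (kind == KIND_TOY) {
    double mu = theta[0] + (eta.n_elem > 0 ? eta[0] : 0.0);
    f.fill(mu);
    return f;
  }
  arma::vec th = theta;
  for (arma::uword j = 0; j < eta.n_elem; ++j)
    th[eta_idx[j]] *= std::exp(eta[j]);
  if (kind == KIND_PK) {
    const double cl = th[0], v = th[1], d2 = th[2], ka = th[3],
                 alag = th[4], rf = th[5];
    const double fz = 1.0 / (1.0 + std::exp(-rf));
    for (int i = 0; i < n; ++i)
      f[i] = conc_one(sd.t[i], sd.dose, cl, v, d2, ka, alag, fz);
    return f;
  }
  // KIND_PD: theta = base kout emax ga ca cb ecb mtt
  const double base = th[0], kout = th[1], emax = th[2], ga = th[3],
               ca = th[4], cb = th[5], ecb = th[6], mtt = th[7];
  const double kin = kout * base, ktr = 1.0 / mtt;
  const int S = (int)sd.stage_t.size();
  std::vector<double> ev(S);
  for (int s = 0; s < S; ++s) {
    const double ts = sd.stage_t[s];
    const double ec50 = ecb * (1.0 + ca * (1.0 - std::exp(-cb * ts)));
    double e = 1.0;
    if (sd.stage_c[s] > 0.0) {
      const double cg = std::exp(ga * sd.stage_logc[s]);
      const double eg = std::exp(ga * std::log(ec50));
      e = 1.0 + emax * cg / (eg + cg);
    }
    ev[s] = e;
  }
  rk4_march(sd.knots, ev, kin, ktr, kout, base, sd.obs_idx, f.memptr());
  return f;
}

// penalized individual -2 log-likelihood
static double subj_nll(const arma::vec& f, const arma::vec& y,
                       const arma::vec& eta, const arma::vec& om2,
                       double sa, double sp) {
  double l = 0.0;
  for (arma::uword i = 0; i < y.n_elem; ++i) {
    const double v = sa * sa + sp * sp * f[i] * f[i];
    const double r = y[i] - f[i];
    l += std::log(2.0 * M_PI * v) + r * r / v;
  }
  for (arma::uword j = 0; j < eta.n_elem; ++j)
    l += eta[j] * eta[j] / om2[j] + std::log(2.0 * M_PI * om2[j]);
  return l;
}

// inner Newton (Gauss-Newton Hessian, finite-difference gradient of the
// full penalized objective).  Returns the Laplace -2 log marginal term.
static double laplace_subj(int kind, const SubjData& sd, const arma::vec& theta,
                           const IntegerVector& eta_idx, const arma::vec& om_sd,
                           double sa, double sp, arma::vec& eta,
                           double h, double tol, int maxit, bool& conv) {
  const int p = (int)om_sd.n_elem;
  conv = true;
  if (p == 0) {
    arma::vec f = predict_subj(kind, sd, theta, eta_idx, arma::vec(), 0);
    return subj_nll(f, sd.y, arma::vec(), arma::vec(), sa, sp);
  }
  arma::vec om2 = arma::square(om_sd);
  arma::vec f0 = predict_subj(kind, sd, theta, eta_idx, eta, 0);
  double l0 = subj_nll(f0, sd.y, eta, om2, sa, sp);
  const int n = (int)sd.y.n_elem;
  arma::mat J(n, p), H(p, p);
  arma::vec g(p);
  if (n == 0) {  // no observations: mode is eta = 0, H = Omega^-1
    eta.zeros();
    double l = subj_nll(arma::vec(), sd.y, eta, om2, sa, sp);
    double ld = 0.0;
    for (int j = 0; j < p; ++j) ld += std::log(1.0 / om2[j]);
    return l - p * LOG2PI + ld;
  }
  for (int it = 0; it < maxit; ++it) {
    for (int j = 0; j < p; ++j) {
      arma::vec ep = eta, em = eta;
      ep[j] += h; em[j] -= h;
      arma::vec fp = predict_subj(kind, sd, theta, eta_idx, ep, 0);
      arma::vec fm = predict_subj(kind, sd, theta, eta_idx, em, 0);
      J.col(j) = (fp - fm) / (2.0 * h);
      g[j] = (subj_nll(fp, sd.y, ep, om2, sa, sp) -
              subj_nll(fm, sd.y, em, om2, sa, sp)) / (2.0 * h);
    }
    arma::vec w(n);
    for (int i = 0; i < n; ++i)
      w[i] = 1.0 / (sa * sa + sp * sp * f0[i] * f0[i]);
    H = J.t() * arma::diagmat(w) * J;
    H.diag() += 1.0 / om2;
    arma::vec step;
    double ridge = 0.0;
    while (!arma::solve(step, H + ridge * arma::eye(p, p), -0.5 * g,
                        arma::solve_opts::likely_sympd)) {
      ridge = (ridge == 0.0) ? 1e-6 : ridge * 100.0;
      if (ridge > 1e6) { conv = false; break; }
    }
    if (!conv) break;
    double lam = 1.0;
    arma::vec etry; arma::vec ftry; double ltry = l0;
    bool ok = false;
    for (int ls = 0; ls < 12; ++ls) {
      etry = eta + lam * step;
      ftry = predict_subj(kind, sd, theta, eta_idx, etry, 0);
      ltry = subj_nll(ftry, sd.y, etry, om2, sa, sp);
      if (ltry <= l0 + 1e-12) { ok = true; break; }
      lam *= 0.5;
    }
    if (!ok) break;  // cannot improve: accept current mode
    const double moved = lam * arma::abs(step).max();
    const double dl = l0 - ltry;
    eta = etry; f0 = ftry; l0 = ltry;
    if (moved < tol || dl < 1e-10) break;
  }
  // Laplace: l(eta_hat) - p log 2pi + log det(J'WJ + Omega^-1)
  arma::vec w(n);
  for (int i = 0; i < n; ++i)
    w[i] = 1.0 / (sa * sa + sp * sp * f0[i] * f0[i]);
  H = J.t() * arma::diagmat(w) * J;
  H.diag() += 1.0 / om2;
  double ldet, sign;
  if (!arma::log_det(ldet, sign, H) || sign <= 0.0) { conv = false; ldet = 0.0; }
  return l0 - p * LOG2PI + ldet;
}

static std::vector<SubjData> unpack_subjects(int kind, List subjects) {
  std::vector<SubjData> out(subjects.size());
  for (int s = 0; s < subjects.size(); ++s) {
    List sub = subjects[s];
    SubjData& sd = out[s];
    sd.t = as<arma::vec>(sub["t"]);
    sd.y = as<arma::vec>(sub["y"]);
    sd.dose = sub.containsElementNamed("dose") ? as<double>(sub["dose"]) : 0.0;
    if (kind == KIND_PD) {
      NumericVector pk = sub["pk"];   // cl v d2 ka alag fz
      sd.cl = pk[0]; sd.v = pk[1]; sd.d2 = pk[2];
      sd.ka = pk[3]; sd.alag = pk[4]; sd.fz = pk[5];
      double dt = as<double>(sub["dt"]);
      NumericVector tt(sd.t.begin(), sd.t.end());
      List grid = cpp_pd_grid(tt, dt);
      NumericVector st = grid["stage_t"], kn = grid["knots"];
      sd.obs_idx = grid["obs_idx"];
      sd.knots.assign(kn.begin(), kn.end());
      sd.stage_t.assign(st.begin(), st.end());
      sd.stage_c.resize(sd.stage_t.size());
      sd.stage_logc.resize(sd.stage_t.size());
      for (size_t i = 0; i < sd.stage_t.size(); ++i) {
        const double c = conc_one(sd.stage_t[i], sd.dose, sd.cl, sd.v,
                                  sd.d2, sd.ka, sd.alag, sd.fz);
        sd.stage_c[i] = c;
        sd.stage_logc[i] = (c > 0.0) ? std::log(c) : 0.0;
      }
    }
  }
  return out;
}

// Population objective: sum over subjects of the Laplace approximation to
// -2 log marginal likelihood.  eta_init (p x nsubj) warm-starts the inner
// optimizations; the converged modes are returned.
// [[Rcpp::export]]
List cpp_laplace_ofv(int kind, List subjects, NumericVector theta,
                     IntegerVector eta_idx, NumericVector omega_sd,
                     NumericVector sigma, NumericMatrix eta_init,
                     double h_inner, double tol_inner, int maxit_inner) {
  std::vector<SubjData> sds = unpack_subjects(kind, subjects);
  const int ns = (int)sds.size();
  const int p = omega_sd.size();
  arma::vec th = as<arma::vec>(theta);
  arma::vec om = as<arma::vec>(omega_sd);
  const double sa = sigma[0], sp = sigma.size() > 1 ? sigma[1] : 0.0;
  NumericMatrix eta_out(p, ns);
  NumericVector ofv_i(ns);
  LogicalVector conv(ns);
  double total = 0.0;
  for (int s = 0; s < ns; ++s) {
    arma::vec eta(p, arma::fill::zeros);
    for (int j = 0; j < p; ++j) eta[j] = eta_init(j, s);
    bool ok = true;
    ofv_i[s] = laplace_subj(kind, sds[s], th, eta_idx, om, sa, sp, eta,
                            h_inner, tol_inner, maxit_inner, ok);
    conv[s] = ok;
    for (int j = 0; j < p; ++j) eta_out(j, s) = eta[j];
    total += ofv_i[s];
  }
  return List::create(_["ofv"] = total, _["ofv_i"] = ofv_i,
                      _["eta"] = eta_out, _["converged"] = conv);
}

// Individual predictions at given eta (used for EBE/IPRED/GOF tables).
// [[Rcpp::export]]
NumericVector cpp_predict_subject(int kind, List subject, NumericVector theta,
                                  IntegerVector eta_idx, NumericVector eta) {
  List wrap = List::create(subject);
  std::vector<SubjData> sds = unpack_subjects(kind, wrap);
  arma::vec f = predict_subj(kind, sds[0], as<arma::vec>(theta), eta_idx,
                             as<arma::vec>(eta), 0);
  return NumericVector(f.begin(), f.end());
}
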