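#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Canonical 9-parameter layout used throughout the compiled core:
//   0 a, 1 gamma, 2 H_LD, 3 tauL_LD, 4 H_SD, 5 tauL_SD, 6 beta_p,
//   7 sigma_c (starch noise SD), 8 sigma_s (sucrose noise SD).
// Internal time unit: one day = 1; time-of-day in [0, 1), dawn at 0.

// Clock-gated degradation rate beta_t. The profile is subjective: its two
// branches switch at the subjective dusk tau_L (the trough), not at the
// external dusk, and the dawn-side limit t -> 1 is the daily peak
// a * tauL * beta_p^kappa. For tauL < 1 - gamma the light-branch numerator
// turns negative (extremely short subjective photoperiod) and is clamped to 0.
// x^kappa with a fast path for the spherical-granule exponent 2/3
static inline double pow_k(double x, double kappa) {
  if (kappa == 2.0 / 3.0) {
    double c = std::cbrt(x);
    return c * c;
  }
  return std::pow(x, kappa);
}

static inline double beta_eval(double tod, bool subj_light, double a,
                               double gamma, double beta_p, double kappa,
                               double tauL) {
  if (subj_light) {
    double num = a * (gamma - 1.0 + tauL);
    if (num <= 0.0) return 0.0;
    return num * pow_k(beta_p, kappa) /
           pow_k(a * beta_p * (1.0 - tauL) * tod + 1.0, kappa);
  }
  return a * tauL * pow_k(beta_p, kappa) /
         pow_k(a * beta_p * tauL * (1.0 - tod) + 1.0, kappa);
}

static inline double beta_gate(double tod, double a, double gamma,
                               double beta_p, double kappa, double tauL) {
  return beta_eval(tod, tod < tauL, a, gamma, beta_p, kappa, tauL);
}

// [[Rcpp::export]]
NumericVector cpp_beta_gate(NumericVector tod, double a, double gamma,
                            double beta_p, double kappa, double tauL) {
  int n = tod.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = beta_gate(tod[i], a, gamma, beta_p, kappa, tauL);
  return out;
}

struct SimPars {
  double a, gamma, beta_p, kappa, H, tauL, P;
};

// One smooth segment of the canonical day, with its stage-grid beta values
// precomputed (the diel beta profile is the same every simulated day, so the
// 2n+1 stage evaluations per segment are shared across days).
struct DaySegment {
  double t0, t1, h;
  int n;
  bool light, subj_light;
  std::vector<double> beta;  // at stage tods t0, t0+h/2, t0+h, ... (2n+1)
};

static inline bool rk4_segment(const DaySegment& seg, const SimPars& sp,
                               double& C, double& S, long& ncap) {
  double h = seg.h;
  for (int i = 0; i < seg.n; ++i) {
    const double* b = &seg.beta[2 * i];
    double k1C, k1S, k2C, k2S, k3C, k3S, k4C, k4S;
    auto stage = [&](double beta, double Ci, double Si, double& dC,
                     double& dS) {
      double Cc = Ci > 0.0 ? Ci : 0.0;
      double deg = beta * pow_k(Cc, sp.kappa);
      if (deg * h > Cc) {
        deg = Cc / h;  // flux cap: a step can never drive starch negative
        ++ncap;
      }
      if (seg.light) {
        dC = sp.a * sp.gamma - deg;
        dS = sp.a * (1.0 - sp.gamma) + deg - sp.H * Si;
      } else {
        dC = -deg;
        dS = deg - sp.H * Si;
      }
    };
    stage(b[0], C, S, k1C, k1S);
    stage(b[1], C + 0.5 * h * k1C, S + 0.5 * h * k1S, k2C, k2S);
    stage(b[1], C + 0.5 * h * k2C, S + 0.5 * h * k2S, k3C, k3S);
    stage(b[2], C + h * k3C, S + h * k3S, k4C, k4S);
    C += h / 6.0 * (k1C + 2.0 * k2C + 2.0 * k3C + k4C);
    S += h / 6.0 * (k1S + 2.0 * k2S + 2.0 * k3S + k4S);
    if (C < 0.0) C = 0.0;
    if (!std::isfinite(C) || !std::isfinite(S)) return false;
  }
  return true;
}

// Integrate n_days days from (C0, S0), reporting the state at out_times
// (absolute time in days, sorted, within [0, n_days]). Segment breakpoints:
// day boundaries, external dusk P, subjective dusk tauL, and the time-of-day
// of every output time (inserted into every day so the day grid is shared),
// so no RK4 step ever straddles a discontinuity.
static bool simulate_core(const SimPars& sp, double C0, double S0, int n_days,
                          double dt, const std::vector<double>& out_times,
                          std::vector<double>& outC, std::vector<double>& outS,
                          long& ncap) {
  const double tol = 1e-12;
  size_t nout = out_times.size();
  outC.assign(nout, NA_REAL);
  outS.assign(nout, NA_REAL);

  // canonical within-day knots shared by all days
  std::vector<double> knots;
  knots.push_back(0.0);
  knots.push_back(sp.P);
  knots.push_back(sp.tauL);
  for (size_t j = 0; j < nout; ++j) {
    double tod = out_times[j] - std::floor(out_times[j] + tol);
    if (tod > tol && tod < 1.0 - tol) knots.push_back(tod);
  }
  knots.push_back(1.0);
  std::sort(knots.begin(), knots.end());
  knots.erase(std::unique(knots.begin(), knots.end(),
                          [tol](double x, double y) {
                            return std::fabs(x - y) < tol;
                          }),
              knots.end());

  std::vector<DaySegment> segs;
  for (size_t k = 0; k + 1 < knots.size(); ++k) {
    DaySegment sg;
    sg.t0 = knots[k];
    sg.t1 = knots[k + 1];
    double len = sg.t1 - sg.t0;
    sg.n = (int)std::ceil(len / dt - 1e-9);
    if (sg.n < 1) sg.n = 1;
    sg.h = len / sg.n;
    double mid = 0.5 * (sg.t0 + sg.t1);
    sg.light = mid < sp.P;
    sg.subj_light = mid < sp.tauL;
    sg.beta.resize(2 * sg.n + 1);
    for (int i = 0; i <= 2 * sg.n; ++i)
      sg.beta[i] = beta_eval(sg.t0 + 0.5 * i * sg.h, sg.subj_light, sp.a,
                             sp.gamma, sp.beta_p, sp.kappa, sp.tauL);
    segs.push_back(sg);
  }

  double C = C0, S = S0;
  size_t iout = 0;
  while (iout < nout && out_times[iout] <= tol) {
    outC[iout] = C;
    outS[iout] = S;
    ++iout;
  }
  for (int day = 0; day < n_days; ++day) {
    for (size_t k = 0; k < segs.size(); ++k) {
      if (!rk4_segment(segs[k], sp, C, S, ncap)) return false;
      double t_end = day + segs[k].t1;
      while (iout < nout && out_times[iout] < t_end - 1e-9) ++iout;
      while (iout < nout && std::fabs(out_times[iout] - t_end) < 1e-9) {
        outC[iout] = C;
        outS[iout] = S;
        ++iout;
      }
    }
  }
  return true;
}

// [[Rcpp::export]]
List cpp_simulate(double a, double gamma, double beta_p, double kappa, double H,
                  double tauL, double P, double C0, double S0, int n_days,
                  double dt, NumericVector out_times) {
  SimPars sp{a, gamma, beta_p, kappa, H, tauL, P};
  std::vector<double> ot(out_times.begin(), out_times.end());
  std::vector<double> C, S;
  long ncap = 0;
  bool ok = simulate_core(sp, C0, S0, n_days, dt, ot, C, S, ncap);
  return List::create(_["C"] = wrap(C), _["S"] = wrap(S), _["ok"] = ok,
                      _["n_capped"] = (double)ncap);
}

struct LikData {
  double P_ld, P_sd, kappa;
  std::vector<double> zt_ld, zt_sd;       // hours in [0, 24]
  std::vector<double> c_ld, s_ld, c_sd, s_sd;
  int n_days;
  double dt;
  std::vector<int> eval_days;  // 1-based day numbers whose profile matches obs
};

static inline double lnorm(double x, double mu, double s2) {
  double r = x - mu;
  return -0.5 * std::log(2.0 * M_PI * s2) - r * r / (2.0 * s2);
}

// Pointwise log-likelihood layout (per eval day, concatenated over days):
// LD starch by ZT, LD sucrose by ZT, SD starch by ZT, SD sucrose by ZT.
static bool loglik_core(const double* th, const LikData& d,
                        std::vector<double>& pw, double& total, long& ncap) {
  double a = th[0], gamma = th[1], beta_p = th[6];
  double s2c = th[7] * th[7], s2s = th[8] * th[8];
  size_t nld = d.zt_ld.size(), nsd = d.zt_sd.size(), nd = d.eval_days.size();
  pw.assign(nd * 2 * (nld + nsd), 0.0);
  total = 0.0;
  for (int cond = 0; cond < 2; ++cond) {
    double H = cond == 0 ? th[2] : th[4];
    double tauL = cond == 0 ? th[3] : th[5];
    double P = cond == 0 ? d.P_ld : d.P_sd;
    const std::vector<double>& zt = cond == 0 ? d.zt_ld : d.zt_sd;
    const std::vector<double>& oc = cond == 0 ? d.c_ld : d.c_sd;
    const std::vector<double>& os = cond == 0 ? d.s_ld : d.s_sd;
    if (a <= 0.0 || H <= 0.0 || beta_p <= 0.0 || s2c <= 0.0 || s2s <= 0.0)
      return false;
    SimPars sp{a, gamma, beta_p, d.kappa, H, tauL, P};
    std::vector<double> ot;
    for (size_t k = 0; k < nd; ++k)
      for (size_t i = 0; i < zt.size(); ++i)
        ot.push_back((d.eval_days[k] - 1) + zt[i] / 24.0);
    std::sort(ot.begin(), ot.end());
    ot.erase(std::unique(ot.begin(), ot.end()), ot.end());
    std::vector<double> C, S;
    if (!simulate_core(sp, 1.0 / beta_p, a * tauL / H, d.n_days, d.dt, ot, C, S,
                       ncap))
      return false;
    for (size_t k = 0; k < nd; ++k) {
      size_t base = k * 2 * (nld + nsd) + (cond == 0 ? 0 : 2 * nld);
      for (size_t i = 0; i < zt.size(); ++i) {
        double t = (d.eval_days[k] - 1) + zt[i] / 24.0;
        size_t j = std::lower_bound(ot.begin(), ot.end(), t - 1e-9) - ot.begin();
        double llc = lnorm(oc[i], C[j], s2c);
        double lls = lnorm(os[i], S[j], s2s);
        pw[base + i] = llc;
        pw[base + zt.size() + i] = lls;
        total += llc + lls;
      }
    }
  }
  return std::isfinite(total);
}

static LikData make_likdata(double P_ld, double P_sd, double kappa,
                            NumericVector zt_ld, NumericVector zt_sd,
                            NumericVector c_ld, NumericVector s_ld,
                            NumericVector c_sd, NumericVector s_sd, int n_days,
                            double dt, IntegerVector eval_days) {
  LikData d;
  d.P_ld = P_ld;
  d.P_sd = P_sd;
  d.kappa = kappa;
  d.zt_ld.assign(zt_ld.begin(), zt_ld.end());
  d.zt_sd.assign(zt_sd.begin(), zt_sd.end());
  d.c_ld.assign(c_ld.begin(), c_ld.end());
  d.s_ld.assign(s_ld.begin(), s_ld.end());
  d.c_sd.assign(c_sd.begin(), c_sd.end());
  d.s_sd.assign(s_sd.begin(), s_sd.end());
  d.n_days = n_days;
  d.dt = dt;
  d.eval_days.assign(eval_days.begin(), eval_days.end());
  return d;
}

// [[Rcpp::export]]
List cpp_loglik(NumericVector theta, double P_ld, double P_sd, double kappa,
                NumericVector zt_ld, NumericVector zt_sd, NumericVector c_ld,
                NumericVector s_ld, NumericVector c_sd, NumericVector s_sd,
                int n_days, double dt, IntegerVector eval_days) {
  LikData d = make_likdata(P_ld, P_sd, kappa, zt_ld, zt_sd, c_ld, s_ld, c_sd,
                           s_sd, n_days, dt, eval_days);
  std::vector<double> pw;
  double total;
  long ncap = 0;
  bool ok = loglik_core(REAL(theta), d, pw, total, ncap);
  if (!ok) total = R_NegInf;
  return List::create(_["total"] = total, _["pointwise"] = wrap(pw),
                      _["ok"] = ok, _["n_capped"] = (double)ncap);
}

static inline double sigmoid(double z) {
  return z > 0.0 ? 1.0 / (1.0 + std::exp(-z)) : std::exp(z) / (1.0 + std::exp(z));
}

// Cholesky factor (lower) of A + eps*I; returns false if not SPD.
static bool chol_lower(const std::vector<double>& A, int n, double eps,
                       std::vector<double>& L) {
  L.assign(n * n, 0.0);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j <= i; ++j) {
      double s = A[i * n + j] + (i == j ? eps : 0.0);
      for (int k = 0; k < j; ++k) s -= L[i * n + k] * L[j * n + k];
      if (i == j) {
        if (s <= 0.0) return false;
        L[i * n + i] = std::sqrt(s);
      } else {
        L[i * n + j] = s / L[j * n + j];
      }
    }
  }
  return true;
}

// Adaptive Metropolis-within-Gibbs on logit-transformed coordinates, with an
// additional covariance-adaptive joint update per sweep (the model's
// parameters are strongly correlated along (a, gamma, H, beta_p) ridges,
// which per-coordinate moves traverse slowly).
// Uniform priors on (lo, hi) per free parameter; the transform contributes
// log|dtheta/dz| = log((hi-lo) p (1-p)) to the log target. Proposal scales are
// tuned toward 44% (coordinate) / 23% (joint) acceptance in batches of 50
// sweeps during warmup only (diminishing adaptation; covariance frozen after
// warmup). Uses R's RNG so set.seed() governs reproducibility.
// [[Rcpp::export]]
List cpp_mwg_chain(NumericVector base, IntegerVector free_idx, NumericVector lo,
                   NumericVector hi, NumericVector init, int n_warmup,
                   int n_iter, double P_ld, double P_sd, double kappa,
                   NumericVector zt_ld, NumericVector zt_sd, NumericVector c_ld,
                   NumericVector s_ld, NumericVector c_sd, NumericVector s_sd,
                   int n_days, double dt, IntegerVector eval_days,
                   double target_accept = 0.44) {
  RNGScope scope;
  LikData d = make_likdata(P_ld, P_sd, kappa, zt_ld, zt_sd, c_ld, s_ld, c_sd,
                           s_sd, n_days, dt, eval_days);
  int nf = free_idx.size();
  std::vector<double> th(base.begin(), base.end());
  std::vector<double> z(nf), ls(nf, std::log(0.5));
  for (int k = 0; k < nf; ++k) {
    double p = (init[k] - lo[k]) / (hi[k] - lo[k]);
    p = std::min(std::max(p, 1e-10), 1.0 - 1e-10);
    z[k] = std::log(p / (1.0 - p));
  }
  long ncap = 0;
  std::vector<double> pw, pw_prop;
  double ll, lp;
  // Welford running mean/covariance of z during warmup, for joint proposals
  std::vector<double> zmean(nf, 0.0), zcov(nf * nf, 0.0), L(nf * nf, 0.0);
  long ncov = 0;
  double ls_joint = std::log(2.38 / std::sqrt((double)nf));
  bool have_L = false;
  auto set_theta = [&](void) {
    for (int k = 0; k < nf; ++k)
      th[free_idx[k]] = lo[k] + (hi[k] - lo[k]) * sigmoid(z[k]);
  };
  auto jac = [&](void) {
    double j = 0.0;
    for (int k = 0; k < nf; ++k) {
      double p = sigmoid(z[k]);
      j += std::log((hi[k] - lo[k]) * p * (1.0 - p));
    }
    return j;
  };
  set_theta();
  if (!loglik_core(th.data(), d, pw, ll, ncap)) ll = R_NegInf;
  lp = ll + jac();
  int nobs = (int)pw.size();
  NumericMatrix draws(n_iter, nf);
  NumericMatrix pwmat(n_iter, nobs);
  NumericVector lp_trace(n_iter);
  std::vector<long> acc(nf, 0), acc_batch(nf, 0);
  long nkeep_updates = 0;
  int batch = 0;
  for (int it = 0; it < n_warmup + n_iter; ++it) {
    for (int k = 0; k < nf; ++k) {
      double z_old = z[k];
      z[k] = z_old + std::exp(ls[k]) * norm_rand();
      set_theta();
      double ll_prop;
      bool ok = loglik_core(th.data(), d, pw_prop, ll_prop, ncap);
      double lp_prop = ok ? ll_prop + jac() : R_NegInf;
      if (std::isfinite(lp_prop) &&
          (lp_prop >= lp || std::log(unif_rand()) < lp_prop - lp)) {
        lp = lp_prop;
        pw.swap(pw_prop);
        if (it < n_warmup) ++acc_batch[k];
        else { ++acc[k]; }
      } else {
        z[k] = z_old;
        set_theta();
      }
      if (it >= n_warmup) ++nkeep_updates;
    }
    // joint covariance-adaptive update (once the covariance is informed).
    // The accumulator restarts halfway through warmup so the proposal
    // covariance reflects the stationary region, not the initial wander.
    if (it < n_warmup) {
      if (it == n_warmup / 2) {
        ncov = 0;
        std::fill(zmean.begin(), zmean.end(), 0.0);
        std::fill(zcov.begin(), zcov.end(), 0.0);
      }
      ++ncov;
      std::vector<double> dold(nf);
      for (int i = 0; i < nf; ++i) dold[i] = z[i] - zmean[i];
      for (int i = 0; i < nf; ++i) zmean[i] += dold[i] / ncov;
      for (int i = 0; i < nf; ++i)
        for (int j = 0; j <= i; ++j) {
          double inc = 0.5 * (dold[i] * (z[j] - zmean[j]) +
                              dold[j] * (z[i] - zmean[i]));
          zcov[i * nf + j] += inc;
          zcov[j * nf + i] = zcov[i * nf + j];
        }
      if (ncov >= 50 && (it + 1) % 25 == 0) {
        std::vector<double> S(nf * nf);
        for (int i = 0; i < nf * nf; ++i)
          S[i] = zcov[i] / (ncov - 1) * (5.6644 / nf);  // 2.38^2 / d scaling
        have_L = chol_lower(S, nf, 1e-8, L);
      }
    }
    if (have_L && nf > 1) {
      int n_joint = nf >= 8 ? 6 : 1;  // full fits need more ridge traversal
      for (int rep = 0; rep < n_joint; ++rep) {
        std::vector<double> xi(nf), zp(z);
        for (int k = 0; k < nf; ++k) xi[k] = norm_rand();
        double s = std::exp(ls_joint);
        for (int i = 0; i < nf; ++i) {
          double step = 0.0;
          for (int k = 0; k <= i; ++k) step += L[i * nf + k] * xi[k];
          zp[i] += s * step;
        }
        std::vector<double> z_old(z);
        z = zp;
        set_theta();
        double ll_prop;
        bool ok = loglik_core(th.data(), d, pw_prop, ll_prop, ncap);
        double lp_prop = ok ? ll_prop + jac() : R_NegInf;
        bool accepted = std::isfinite(lp_prop) &&
                        (lp_prop >= lp || std::log(unif_rand()) < lp_prop - lp);
        if (accepted) {
          lp = lp_prop;
          pw.swap(pw_prop);
        } else {
          z = z_old;
          set_theta();
        }
        if (it < n_warmup) {
          double g = std::min(0.1, 2.0 / std::sqrt((double)(it + 1)));
          ls_joint += g * ((accepted ? 1.0 : 0.0) - 0.23);
        }
      }
    }
    if (it < n_warmup && (it + 1) % 50 == 0) {
      ++batch;
      double delta = std::min(0.05, 1.0 / std::sqrt((double)batch));
      for (int k = 0; k < nf; ++k) {
        ls[k] += (acc_batch[k] / 50.0 > target_accept) ? delta : -delta;
        acc_batch[k] = 0;
      }
    }
    if (it >= n_warmup) {
      int row = it - n_warmup;
      for (int k = 0; k < nf; ++k) draws(row, k) = th[free_idx[k]];
      for (int j = 0; j < nobs; ++j) pwmat(row, j) = pw[j];
      lp_trace[row] = lp;
    }
    if (it % 200 == 0) Rcpp::checkUserInterrupt();
  }
  NumericVector accept(nf);
  for (int k = 0; k < nf; ++k) accept[k] = acc[k] / (double)n_iter;
  return List::create(_["draws"] = draws, _["pointwise"] = pwmat,
                      _["lp"] = lp_trace, _["accept"] = accept,
                      _["n_capped"] = (double)ncap,
                      _["prop_scale"] = exp(NumericVector(ls.begin(), ls.end())));
}
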