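#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Generalized Lotka-Volterra competition system for an incumbent
// hunter-gatherer population (HG) and a migrant farmer population (F):
//
//   dHG/dt = gamma_hg * HG * (1 - HG/K_hg) - delta_hg * HG * F
//   dF/dt  = gamma_f_total * F * (1 - F/K_f) + eta * I_hg - delta_f * HG * F
//
// with I_hg = delta_hg * HG * F the interaction-loss flux of the
// hunter-gatherers and gamma_f_total = gamma_f + mu the total farmer growth
// (endogenous growth plus external migration).

struct LVPars {
  double ghg, gft, dhg, df, eta, iKhg, iKf;
};

static inline void lv_deriv(double HG, double F, const LVPars &p,
                            double &dHG, double &dF) {
  const double I_hg = p.dhg * HG * F;
  dHG = p.ghg * HG * (1.0 - HG * p.iKhg) - I_hg;
  dF  = p.gft * F  * (1.0 - F  * p.iKf) + p.eta * I_hg - p.df * HG * F;
}

static int substeps(double step) {
  const double nsub_d = 1.0 / step;
  const int nsub = (int) std::lround(nsub_d);
  if (step <= 0.0 || nsub < 1 || std::fabs(nsub_d - nsub) > 1e-8)
    stop("step must divide 1 year evenly");
  return nsub;
}

// Fixed-step classical Runge-Kutta (RK4) with annual dense output into
// caller-provided buffers (length horizon + 1).  States are clipped at zero
// from below; populations below clip_tol are set to exactly zero so that
// extinction is an absorbing state shared with any finer-step solve.
static void integrate_buf(const LVPars &p, double HG0, double F0,
                          int horizon, int nsub, double clip_tol,
                          double *HGout, double *Fout) {
  const double h = 1.0 / nsub;
  double HG = HG0, F = F0;
  if (HG < clip_tol) HG = 0.0;
  if (F  < clip_tol) F  = 0.0;
  HGout[0] = HG;
  Fout[0] = F;
  double k1h, k1f, k2h, k2f, k3h, k3f, k4h, k4f;
  for (int yr = 1; yr <= horizon; ++yr) {
    for (int s = 0; s < nsub; ++s) {
      lv_deriv(HG, F, p, k1h, k1f);
      lv_deriv(HG + 0.5 * h * k1h, F + 0.5 * h * k1f, p, k2h, k2f);
      lv_deriv(HG + 0.5 * h * k2h, F + 0.5 * h * k2f, p, k3h, k3f);
      lv_deriv(HG + h * k3h, F + h * k3f, p, k4h, k4f);
      HG += h / 6.0 * (k1h + 2.0 * k2h + 2.0 * k3h + k4h);
      F  += h / 6.0 * (k1f + 2.0 * k2f + 2.0 * k3f + k4f);
      if (HG < clip_tol) HG = 0.0;
      if (F  < clip_tol) F  = 0.0;
    }
    HGout[yr] = HG;
    Fout[yr] = F;
  }
}

// [[Rcpp::export(name = ".lv_integrate_cpp")]]
NumericMatrix lv_integrate_cpp(double gamma_hg, double gamma_f_total,
                               double delta_hg, double delta_f, double eta,
                               double K_hg, double K_f,
                               double HG0, double F0,
                               int horizon, double step, double clip_tol) {
  if (horizon < 1) stop("horizon must be >= 1");
  const int nsub = substeps(step);
  const LVPars p = {gamma_hg, gamma_f_total, delta_hg, delta_f, eta,
                    1.0 / K_hg, 1.0 / K_f};
  NumericMatrix out(horizon + 1, 2);
  std::vector<double> hg((size_t) horizon + 1), f((size_t) horizon + 1);
  integrate_buf(p, HG0, F0, horizon, nsub, clip_tol, hg.data(), f.data());
  for (int i = 0; i <= horizon; ++i) {
    out(i, 0) = hg[(size_t) i];
    out(i, 1) = f[(size_t) i];
  }
  return out;
}

// Windowed, per-date-normalized calibrated-density sums for a labelled
// sample of radiocarbon dates: the inner loop of candidate-SPD simulation.
// Each date's density over the full curve grid is
//   dens_i \propto exp(-(mu_i - cra)^2 / (2 s2_i)) / sqrt(s2_i),
//   s2_i = sd^2 + curve_sigma_i^2,
// normalized to unit mass over the full support (evaluated within tail_sd
// composed standard deviations), then summed over the window [i0, i1]
// (0-based, ascending calBP) into the hunter-gatherer or farmer SPD
// according to the date's label.
// [[Rcpp::export(name = ".spd_sample_cpp")]]
List spd_sample_cpp(NumericVector cra, NumericVector sd, LogicalVector farmer,
                    NumericVector mu, NumericVector sig2,
                    int i0, int i1, double tail_sd) {
  const int G = mu.size(), n = cra.size(), W = i1 - i0 + 1;
  if (i0 < 0 || i1 >= G || W < 1) stop("invalid window indices");
  NumericVector hg(W), f(W);
  std::vector<double> col((size_t) W);
  const double t2 = tail_sd * tail_sd;
  for (int j = 0; j < n; ++j) {
    const double sd2 = sd[j] * sd[j], c = cra[j];
    double tot = 0.0;
    std::fill(col.begin(), col.end(), 0.0);
    for (int i = 0; i < G; ++i) {
      const double s2 = sd2 + sig2[i];
      const double d = mu[i] - c;
      const double z2 = d * d / s2;
      if (z2 <= t2) {
        const double v = std::exp(-0.5 * z2) / std::sqrt(s2);
        tot += v;
        if (i >= i0 && i <= i1) col[(size_t)(i - i0)] = v;
      }
    }
    if (tot <= 0.0)
      stop("sampled date %g BP lies outside the calibration curve span", c);
    NumericVector &dst = farmer[j] ? f : hg;
    for (int k = 0; k < W; ++k) dst[k] += col[(size_t) k] / tot;
  }
  return List::create(Named("hg") = hg, Named("f") = f);
}

// ---------------------------------------------------------------------------
// Batch ABC engine.  The sequential rejection and SMC loops run ~10^5-10^6
// model simulations per fit, so the whole candidate pipeline (integrate ->
// sample labelled dates -> uncalibrate -> recalibrate -> SPD pair ->
// distance) is compiled.  Randomness uses R's RNG stream (seed-reproducible
// from R); the draw sequence differs from the R-level reference path, which
// remains the behavioural oracle in the tests.

struct CaseData {
  NumericVector obs_hg, obs_f;   // observed SPD pair, ascending calBP
  NumericVector mu, sig2, calbp; // calibration curve on the annual grid
  NumericVector sd_pool;         // measurement-error pool
  int n_dates, horizon, nsub;
  int gi0;                       // 0-based grid index of trajectory t = 0
  double kf_ratio, step, clip_tol, tail_sd;
  double curve_D;                // max |mu - calbp| over the grid
  double sig2max;
};

static CaseData case_from_list(List cs) {
  CaseData cd;
  cd.obs_hg = cs["obs_hg"];
  cd.obs_f = cs["obs_f"];
  cd.mu = cs["mu"];
  cd.sig2 = cs["sig2"];
  cd.calbp = cs["calbp"];
  cd.sd_pool = cs["sd_pool"];
  cd.n_dates = as<int>(cs["n_dates"]);
  cd.horizon = as<int>(cs["horizon"]);
  cd.gi0 = as<int>(cs["gi0"]);
  cd.kf_ratio = as<double>(cs["kf_ratio"]);
  cd.step = as<double>(cs["step"]);
  cd.clip_tol = as<double>(cs["clip_tol"]);
  cd.tail_sd = as<double>(cs["tail_sd"]);
  cd.nsub = substeps(cd.step);
  if (cd.gi0 - cd.horizon < 0 || cd.gi0 >= cd.mu.size())
    stop("analysis window falls outside the calibration curve grid");
  if (cd.obs_hg.size() != cd.horizon + 1 || cd.obs_f.size() != cd.horizon + 1)
    stop("observed SPDs do not match the window grid");
  double D = 0.0, s2m = 0.0;
  for (int i = 0; i < cd.mu.size(); ++i) {
    D = std::max(D, std::fabs(cd.mu[i] - cd.calbp[i]));
    s2m = std::max(s2m, cd.sig2[i]);
  }
  cd.curve_D = D;
  cd.sig2max = s2m;
  return cd;
}

// exp(-u) on u in [0, 12.5] by linear interpolation of a fixed table;
// relative error < 5e-7, far below the SPD sampling noise the distances
// measure.
#define EXPTAB_N 8192
#define EXPTAB_UMAX 12.5
static double exptab[EXPTAB_N + 2];
static bool exptab_ready = false;
static inline double exp_neg(double u) {
  if (!exptab_ready) {
    for (int i = 0; i <= EXPTAB_N + 1; ++i)
      exptab[i] = std::exp(-EXPTAB_UMAX * i / EXPTAB_N);
    exptab_ready = true;
  }
  const double x = u * (EXPTAB_N / EXPTAB_UMAX);
  const int i = (int) x;
  const double fr = x - i;
  return exptab[i] * (1.0 - fr) + exptab[i + 1] * fr;
}

// per-measurement-error cache of 1/sqrt(sd^2 + curve_sigma^2) on the grid;
// observed-date pools hold few distinct errors, so hits dominate
struct SigCache {
  std::vector<std::pair<double, std::vector<double> > > entries;
  const std::vector<double> *lookup(double sd, const NumericVector &sig2) {
    for (size_t k = 0; k < entries.size(); ++k)
      if (entries[k].first == sd) return &entries[k].second;
    std::vector<double> w((size_t) sig2.size());
    const double sd2 = sd * sd;
    for (int i = 0; i < sig2.size(); ++i)
      w[(size_t) i] = 1.0 / std::sqrt(sd2 + sig2[i]);
    entries.push_back(std::make_pair(sd, w));
    return &entries.back().second;
  }
};

// theta: gamma_hg, gamma_f, mu, delta_hg, delta_f, eta, rho, HG0
static double sim_eps(const double *theta, const CaseData &cd,
                      SigCache &cache,
                      std::vector<double> &hgb, std::vector<double> &fb,
                      std::vector<double> &cumw,
                      std::vector<double> &spd_hg, std::vector<double> &spd_f,
                      std::vector<double> &scratch) {
  const double HG0 = theta[7];
  const LVPars p = {theta[0], theta[1] + theta[2], theta[3], theta[4],
                    theta[5], 1.0 / HG0, 1.0 / (cd.kf_ratio * HG0)};
  const int H = cd.horizon, W = H + 1, G = cd.mu.size();
  integrate_buf(p, HG0, theta[6] * HG0, H, cd.nsub, cd.clip_tol,
                hgb.data(), fb.data());
  double tot = 0.0;
  for (int i = 0; i < W; ++i) {
    tot += hgb[(size_t) i] + fb[(size_t) i];
    cumw[(size_t) i] = tot;
  }
  if (tot <= 0.0) return R_PosInf;
  std::fill(spd_hg.begin(), spd_hg.end(), 0.0);
  std::fill(spd_f.begin(), spd_f.end(), 0.0);
  const int npool = cd.sd_pool.size();
  const double t2 = cd.tail_sd * cd.tail_sd;
  const int iw0 = cd.gi0 - H;  // ascending-grid window indices [iw0, gi0]
  for (int k = 0; k < cd.n_dates; ++k) {
    // calendar year from the discretized total density
    const double u = unif_rand() * tot;
    const int ti = (int) (std::upper_bound(cumw.begin(), cumw.end(), u) -
                          cumw.begin());
    const int t = std::min(ti, H);
    // binomial population label
    const double w = hgb[(size_t) t] + fb[(size_t) t];
    const bool farmer = unif_rand() < fb[(size_t) t] / w;
    // measurement error resampled from the observed pool
    int pi = (int) (unif_rand() * npool);
    if (pi >= npool) pi = npool - 1;
    const double sdk = cd.sd_pool[pi];
    // uncalibrate: conventional age with composed curve + measurement noise
    const int gi = cd.gi0 - t;
    const double cra = R::rnorm(cd.mu[gi],
                                std::sqrt(sdk * sdk + cd.sig2[gi]));
    // recalibrate: single pass over the support band into a scratch
    // buffer, then add the normalized values falling inside the window
    const double sd2 = sdk * sdk;
    const double band = cd.tail_sd * std::sqrt(sd2 + cd.sig2max) +
      cd.curve_D + 1.0;
    int lo = (int) std::floor(cra - band) - (int) cd.calbp[0];
    int hi = (int) std::ceil(cra + band) - (int) cd.calbp[0];
    lo = std::max(lo, 0);
    hi = std::min(hi, G - 1);
    if (lo > hi) return R_PosInf;  // date fell off the curve span
    const std::vector<double> &isig = *cache.lookup(sdk, cd.sig2);
    scratch.resize((size_t)(hi - lo + 1));
    double dtot = 0.0;
    for (int i = lo; i <= hi; ++i) {
      const double w = isig[(size_t) i];
      const double zd = (cd.mu[i] - cra) * w;
      const double z2 = zd * zd;
      const double v = (z2 <= t2) ? exp_neg(0.5 * z2) * w : 0.0;
      scratch[(size_t)(i - lo)] = v;
      dtot += v;
    }
    if (dtot <= 0.0) return R_PosInf;
    std::vector<double> &dst = farmer ? spd_f : spd_hg;
    const int a = std::max(lo, iw0), b = std::min(hi, cd.gi0);
    for (int i = a; i <= b; ++i)
      dst[(size_t)(i - iw0)] += scratch[(size_t)(i - lo)] / dtot;
  }
  double mass = 0.0;
  for (int i = 0; i < W; ++i) mass += spd_hg[(size_t) i] + spd_f[(size_t) i];
  if (mass <= 0.0) return R_PosInf;
  double sh = 0.0, sf = 0.0;
  for (int i = 0; i < W; ++i) {
    const double dh = spd_hg[(size_t) i] / mass - cd.obs_hg[i];
    const double df = spd_f[(size_t) i] / mass - cd.obs_f[i];
    sh += dh * dh;
    sf += df * df;
  }
  return std::sqrt(sh) + std::sqrt(sf);
}

// Distances for a batch of parameter draws (rejection stage).
// [[Rcpp::export(name = ".abc_batch_cpp")]]
NumericVector abc_batch_cpp(NumericMatrix theta, List cs) {
  const CaseData cd = case_from_list(cs);
  if (theta.ncol() != 8) stop("theta must have 8 columns");
  const int n = theta.nrow(), W = cd.horizon + 1;
  std::vector<double> hgb(W), fb(W), cumw(W), sh(W), sf(W), th(8), scratch;
  SigCache cache;
  NumericVector eps(n);
  RNGScope scope;
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < 8; ++j) th[(size_t) j] = theta(i, j);
    eps[i] = sim_eps(th.data(), cd, cache, hgb, fb, cumw, sh, sf, scratch);
    if (i % 256 == 0) checkUserInterrupt();
  }
  return eps;
}

// One SMC stage: resample-perturb-accept until `keep` particles pass below
// eps_thr.  Perturbation kernel: independent U(x - w, x + w) per parameter
// with w = max(0.2 |x|, 1e-4 prior width), redrawn until inside the prior
// support.  Errors out ("stall") after max_attempts proposals.
// [[Rcpp::export(name = ".abc_smc_stage_cpp")]]
List abc_smc_stage_cpp(NumericMatrix particles, double eps_thr,
                       NumericVector prior_lo, NumericVector prior_hi,
                       int max_attempts, List cs) {
  const CaseData cd = case_from_list(cs);
  const int keep = particles.nrow();
  if (particles.ncol() != 8 || prior_lo.size() != 8 || prior_hi.size() != 8)
    stop("particles must have 8 columns matching the priors");
  const int W = cd.horizon + 1;
  std::vector<double> hgb(W), fb(W), cumw(W), sh(W), sf(W), th(8), scratch;
  SigCache cache;
  NumericMatrix out(keep, 8);
  NumericVector out_eps(keep);
  int n_acc = 0, attempts = 0;
  RNGScope scope;
  while (n_acc < keep) {
    if (++attempts > max_attempts)
      stop("SMC stage stalled: %d accepted of %d after %d attempts (tolerance %g)",
           n_acc, keep, attempts - 1, eps_thr);
    int src = (int) (unif_rand() * keep);
    if (src >= keep) src = keep - 1;
    for (int j = 0; j < 8; ++j) {
      const double x = particles(src, j);
      const double w = std::max(0.2 * std::fabs(x),
                                1e-4 * (prior_hi[j] - prior_lo[j]));
      double v;
      do {
        v = x - w + 2.0 * w * unif_rand();
      } while (v < prior_lo[j] || v > prior_hi[j]);
      th[(size_t) j] = v;
    }
    const double eps = sim_eps(th.data(), cd, cache, hgb, fb, cumw, sh, sf, scratch);
    if (eps < eps_thr) {
      for (int j = 0; j < 8; ++j) out(n_acc, j) = th[(size_t) j];
      out_eps[n_acc] = eps;
      ++n_acc;
    }
    if (attempts % 256 == 0) checkUserInterrupt();
  }
  return List::create(Named("particles") = out, Named("epsilon") = out_eps,
                      Named("attempts") = attempts);
}
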