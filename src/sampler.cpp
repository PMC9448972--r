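// Adaptive random-walk Metropolis-within-Gibbs sampler for the two-stage
// hierarchical model: binomial egg->larva survival with a complementary
// log-log link (Weibull hazard) and Poisson larva->egg productivity, both
// with normal random year effects.
//
// Parameter vector layout (shared with the R side, see pack_theta):
//   [ survival fixed | sigma_eps | eps_1..eps_T |
//     productivity fixed | sigma_eta | eta_1..eta_R ]
// Survival fixed effects are ordered (a, b, [c], [g_temp]); productivity
// (mu, f, [w...]) with covariate columns in Xw in the same order.

#include <Rcpp.h>
using namespace Rcpp;

namespace {

// log(1 - exp(-h)) for h > 0, stable near both ends
inline double log1mexp(double h) {
  return (h > M_LN2) ? std::log1p(-std::exp(-h)) : std::log(-std::expm1(-h));
}

inline double clip700(double x) {
  if (x > 700.0) return 700.0;
  if (x < -700.0) return -700.0;
  return x;
}

struct FitData {
  NumericVector E, L, logE, logd, temp;
  NumericVector lchooseEL;          // binomial coefficients, precomputed
  int use_d, use_temp;
  NumericVector Lprev, logLprev, Eobs, lgamEobs;
  NumericMatrix Xw;
  double B, scale;
  int T, R, n_w;

  explicit FitData(const List& dat)
    : E(dat["E"]), L(dat["L"]), logE(dat["logE"]), logd(dat["logd"]),
      temp(dat["temp"]),
      use_d(as<int>(dat["use_d"])), use_temp(as<int>(dat["use_temp"])),
      Lprev(dat["Lprev"]), logLprev(dat["logLprev"]), Eobs(dat["Eobs"]),
      Xw(as<NumericMatrix>(dat["Xw"])),
      B(as<double>(dat["B"])), scale(as<double>(dat["scale"])) {
    T = E.size();
    R = Lprev.size();
    n_w = Xw.ncol();
    lchooseEL = NumericVector(T);
    lgamEobs = NumericVector(R);
    for (int t = 0; t < T; ++t) lchooseEL[t] = Rf_lchoose(E[t], L[t]);
    for (int i = 0; i < R; ++i) lgamEobs[i] = std::lgamma(Eobs[i] + 1.0);
  }
};

// fixed (non random-effect) part of the survival linear predictor
void surv_lp0(const FitData& d, const double* sfix, std::vector<double>& lp0) {
  int j = 2;
  double c = 0.0, g = 0.0;
  if (d.use_d) c = sfix[j++];
  if (d.use_temp) g = sfix[j++];
  for (int t = 0; t < d.T; ++t) {
    double lp = sfix[0] + sfix[1] * d.logE[t];
    if (d.use_d) lp += c * d.logd[t];
    if (d.use_temp) lp += g * d.temp[t];
    lp0[t] = lp;
  }
}

inline double surv_ll_year(const FitData& d, int t, double lp) {
  double h = std::exp(-clip700(lp));
  return d.lchooseEL[t] - d.L[t] * h + (d.E[t] - d.L[t]) * log1mexp(h);
}

double surv_ll(const FitData& d, const std::vector<double>& lp0,
               const double* eps) {
  double s = 0.0;
  for (int t = 0; t < d.T; ++t) s += surv_ll_year(d, t, lp0[t] + eps[t]);
  return s;
}

// fixed part of the productivity log per-capita rate
void prod_lq0(const FitData& d, const double* pfix, std::vector<double>& lq0) {
  for (int i = 0; i < d.R; ++i) {
    double lq = pfix[0] + pfix[1] * d.logLprev[i];
    for (int w = 0; w < d.n_w; ++w) lq += pfix[2 + w] * d.Xw(i, w);
    lq0[i] = lq;
  }
}

inline double prod_ll_trans(const FitData& d, int i, double lq) {
  // E_t ~ Poisson(Lprev * exp(lq)); log lambda = log Lprev + lq
  double loglam = d.logLprev[i] + clip700(lq);
  return d.Eobs[i] * loglam - std::exp(loglam) - d.lgamEobs[i];
}

double prod_ll(const FitData& d, const std::vector<double>& lq0,
               const double* eta) {
  double s = 0.0;
  for (int i = 0; i < d.R; ++i) s += prod_ll_trans(d, i, lq0[i] + eta[i]);
  return s;
}

inline double half_cauchy_lpdf(double x, double scale) {
  if (x <= 0) return R_NegInf;
  return std::log(2.0 / (M_PI * scale)) - std::log1p((x / scale) * (x / scale));
}

inline double norm_lpdf(double x, double sd) {
  return -0.5 * std::log(2.0 * M_PI) - std::log(sd) -
         0.5 * (x / sd) * (x / sd);
}

double re_prior(const double* z, int n, double sd) {
  double s = 0.0;
  for (int i = 0; i < n; ++i) s += norm_lpdf(z[i], sd);
  return s;
}

// lower Cholesky factor of a small SPD matrix (row-major); false on failure
bool cholesky_small(const std::vector<double>& A, int n,
                    std::vector<double>& Lc) {
  Lc.assign(n * n, 0.0);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j <= i; ++j) {
      double s = A[i * n + j];
      for (int k = 0; k < j; ++k) s -= Lc[i * n + k] * Lc[j * n + k];
      if (i == j) {
        if (s <= 0) return false;
        Lc[i * n + i] = std::sqrt(s);
      } else {
        Lc[i * n + j] = s / Lc[j * n + j];
      }
    }
  }
  return true;
}

// running mean / scatter for the adaptive block proposals
struct BlockAdapt {
  int n = 0;
  long k = 0;
  std::vector<double> mean, M2, chol;
  double lscale = std::log(0.3);
  bool have_chol = false;

  void init(int dim) {
    n = dim;
    mean.assign(n, 0.0);
    M2.assign(n * n, 0.0);
  }
  void update(const double* x) {
    ++k;
    std::vector<double> d(n);
    for (int i = 0; i < n; ++i) {
      d[i] = x[i] - mean[i];
      mean[i] += d[i] / k;
    }
    for (int i = 0; i < n; ++i) {
      for (int j = 0; j <= i; ++j) {
        double v = d[i] * (x[j] - mean[j]);
        M2[i * n + j] += v;
        if (i != j) M2[j * n + i] += v;
      }
    }
  }
  void refresh_chol() {
    if (k < 10 * n) return;
    std::vector<double> cov(n * n);
    for (int i = 0; i < n * n; ++i) cov[i] = M2[i] / (k - 1);
    for (int i = 0; i < n; ++i) cov[i * n + i] += 1e-8;
    std::vector<double> Lc;
    if (cholesky_small(cov, n, Lc)) {
      chol = Lc;
      have_chol = true;
    }
  }
  void propose(const double* cur, double* prop) const {
    double sc = std::exp(lscale);
    std::vector<double> z(n);
    for (int i = 0; i < n; ++i) z[i] = norm_rand();
    if (have_chol) {
      for (int i = 0; i < n; ++i) {
        double s = 0.0;
        for (int j = 0; j <= i; ++j) s += chol[i * n + j] * z[j];
        prop[i] = cur[i] + sc * s;
      }
    } else {
      for (int i = 0; i < n; ++i) prop[i] = cur[i] + sc * z[i];
    }
  }
};

}  // namespace

// Full joint log posterior for a flat parameter vector; reference value
// used by the R-side cross-checks and by the sampler's scalar updates.
// [[Rcpp::export]]
double cpp_log_posterior(List dat, NumericVector theta, int n_sfix,
                         int n_pfix) {
  FitData d(dat);
  const double* th = theta.begin();
  const double* sfix = th;
  double sigma_eps = th[n_sfix];
  const double* eps = th + n_sfix + 1;
  const double* pfix = eps + d.T;
  double sigma_eta = pfix[n_pfix];
  const double* eta = pfix + n_pfix + 1;

  double lp = 0.0;
  for (int i = 0; i < n_sfix; ++i) {
    if (std::fabs(sfix[i]) >= d.B) return R_NegInf;
    lp += -std::log(2.0 * d.B);
  }
  for (int i = 0; i < n_pfix; ++i) {
    if (std::fabs(pfix[i]) >= d.B) return R_NegInf;
    lp += -std::log(2.0 * d.B);
  }
  if (sigma_eps <= 0 || sigma_eta <= 0) return R_NegInf;
  lp += half_cauchy_lpdf(sigma_eps, d.scale);
  lp += half_cauchy_lpdf(sigma_eta, d.scale);
  lp += re_prior(eps, d.T, sigma_eps);
  lp += re_prior(eta, d.R, sigma_eta);

  std::vector<double> lp0(d.T), lq0(d.R);
  surv_lp0(d, sfix, lp0);
  prod_lq0(d, pfix, lq0);
  lp += surv_ll(d, lp0, eps);
  lp += prod_ll(d, lq0, eta);
  return lp;
}

// One MCMC chain. Scalar fixed effects and SDs get adaptive random-walk
// Metropolis updates (Robbins-Monro step-size adaptation toward 0.44
// acceptance during warmup, frozen afterwards); the per-year random
// effects, conditionally independent given everything else, get
// vectorised single-site updates. Uses R's RNG so set.seed() on the R
// side makes chains reproducible.
// [[Rcpp::export]]
List cpp_run_chain(List dat, NumericVector init, int n_sfix, int n_pfix,
                   int n_iter, int n_warmup, int thin) {
  FitData d(dat);
  const int T = d.T, R = d.R;
  const int i_sig_eps = n_sfix;
  const int i_eps = n_sfix + 1;
  const int i_pfix = i_eps + T;
  const int i_sig_eta = i_pfix + n_pfix;
  const int i_eta = i_sig_eta + 1;
  const int n_par = i_eta + R;
  if (init.size() != n_par) stop("init has wrong length");

  std::vector<double> th(init.begin(), init.end());
  if (th[i_sig_eps] <= 0) th[i_sig_eps] = 0.5;
  if (th[i_sig_eta] <= 0) th[i_sig_eta] = 0.5;

  std::vector<double> lp0(T), lq0(R);
  surv_lp0(d, &th[0], lp0);
  prod_lq0(d, &th[i_pfix], lq0);
  double sll = surv_ll(d, lp0, &th[i_eps]);
  double pll = prod_ll(d, lq0, &th[i_eta]);

  std::vector<double> ls(n_par, std::log(0.1));  // log proposal SDs
  std::vector<double> acc(n_par, 0.0);
  std::vector<long> ntry(n_par, 0);
  const double target = 0.44;

  int n_keep = (n_iter - n_warmup) / thin;
  NumericMatrix draws(n_keep, n_par);
  int kept = 0;

  std::vector<double> prop_lp0(T), prop_lq0(R);

  // adaptive correlated proposals for the two fixed-effect blocks, which
  // are the strongly correlated directions of this posterior
  BlockAdapt ba_s, ba_p;
  ba_s.init(n_sfix);
  ba_p.init(n_pfix);
  const double btarget = 0.234;
  std::vector<double> bprop(std::max(n_sfix, n_pfix));

  // covariate columns of each fixed effect, for the likelihood-invariant
  // trade-off moves against the random effects
  std::vector<std::vector<double>> sxcov(n_sfix, std::vector<double>(T, 1.0));
  {
    int j = 1;
    for (int t = 0; t < T; ++t) sxcov[j][t] = d.logE[t];
    ++j;
    if (d.use_d) { for (int t = 0; t < T; ++t) sxcov[j][t] = d.logd[t]; ++j; }
    if (d.use_temp) { for (int t = 0; t < T; ++t) sxcov[j][t] = d.temp[t]; }
  }
  std::vector<std::vector<double>> pxcov(n_pfix, std::vector<double>(R, 1.0));
  for (int i = 0; i < R; ++i) pxcov[1][i] = d.logLprev[i];
  for (int w = 0; w < d.n_w; ++w) {
    for (int i = 0; i < R; ++i) pxcov[2 + w][i] = d.Xw(i, w);
  }
  std::vector<double> ls_tilt_s(n_sfix, std::log(0.3));
  std::vector<double> ls_tilt_p(n_pfix, std::log(0.3));

  for (int it = 0; it < n_iter; ++it) {
    bool adapt = it < n_warmup;
    double gamma = adapt ? std::pow(it + 1.0, -0.6) : 0.0;

    // --- survival fixed effects ---
    for (int j = 0; j < n_sfix; ++j) {
      double cur = th[j];
      double prop = cur + std::exp(ls[j]) * norm_rand();
      double alpha = 0.0;
      if (std::fabs(prop) < d.B) {
        th[j] = prop;
        surv_lp0(d, &th[0], prop_lp0);
        double prop_sll = surv_ll(d, prop_lp0, &th[i_eps]);
        alpha = std::min(1.0, std::exp(prop_sll - sll));
        if (unif_rand() < alpha) {
          sll = prop_sll;
          lp0.swap(prop_lp0);
        } else {
          th[j] = cur;
        }
      }
      ntry[j]++; acc[j] += alpha;
      if (adapt) ls[j] += gamma * (alpha - target);
    }

    // --- survival fixed effects: joint adapted block ---
    {
      ba_s.propose(&th[0], &bprop[0]);
      bool inb = true;
      for (int j = 0; j < n_sfix; ++j) {
        if (std::fabs(bprop[j]) >= d.B) inb = false;
      }
      double alpha = 0.0;
      if (inb) {
        std::vector<double> save(th.begin(), th.begin() + n_sfix);
        for (int j = 0; j < n_sfix; ++j) th[j] = bprop[j];
        surv_lp0(d, &th[0], prop_lp0);
        double prop_sll = surv_ll(d, prop_lp0, &th[i_eps]);
        alpha = std::min(1.0, std::exp(prop_sll - sll));
        if (unif_rand() < alpha) {
          sll = prop_sll;
          lp0.swap(prop_lp0);
        } else {
          for (int j = 0; j < n_sfix; ++j) th[j] = save[j];
        }
      }
      if (adapt) {
        ba_s.lscale += gamma * (alpha - btarget);
        ba_s.update(&th[0]);
        if ((it + 1) % 100 == 0) ba_s.refresh_chol();
      }
    }

    // --- sigma_eps (changes only the eps prior + its own prior) ---
    {
      int j = i_sig_eps;
      double cur = th[j];
      double prop = cur + std::exp(ls[j]) * norm_rand();
      double alpha = 0.0;
      if (prop > 0) {
        double dlt = half_cauchy_lpdf(prop, d.scale) -
                     half_cauchy_lpdf(cur, d.scale) +
                     re_prior(&th[i_eps], T, prop) -
                     re_prior(&th[i_eps], T, cur);
        alpha = std::min(1.0, std::exp(dlt));
        if (unif_rand() < alpha) th[j] = prop;
      }
      ntry[j]++; acc[j] += alpha;
      if (adapt) ls[j] += gamma * (alpha - target);
    }

    // --- eps: single-site vectorised ---
    for (int t = 0; t < T; ++t) {
      int j = i_eps + t;
      double cur = th[j];
      double prop = cur + std::exp(ls[j]) * norm_rand();
      double cur_ll = surv_ll_year(d, t, lp0[t] + cur);
      double prop_ll = surv_ll_year(d, t, lp0[t] + prop);
      double dlt = prop_ll - cur_ll +
                   norm_lpdf(prop, th[i_sig_eps]) -
                   norm_lpdf(cur, th[i_sig_eps]);
      double alpha = std::min(1.0, std::exp(dlt));
      if (unif_rand() < alpha) {
        th[j] = prop;
        sll += prop_ll - cur_ll;
      }
      ntry[j]++; acc[j] += alpha;
      if (adapt) ls[j] += gamma * (alpha - target);
    }

    // --- productivity fixed effects ---
    for (int jj = 0; jj < n_pfix; ++jj) {
      int j = i_pfix + jj;
      double cur = th[j];
      double prop = cur + std::exp(ls[j]) * norm_rand();
      double alpha = 0.0;
      if (std::fabs(prop) < d.B) {
        th[j] = prop;
        prod_lq0(d, &th[i_pfix], prop_lq0);
        double prop_pll = prod_ll(d, prop_lq0, &th[i_eta]);
        alpha = std::min(1.0, std::exp(prop_pll - pll));
        if (unif_rand() < alpha) {
          pll = prop_pll;
          lq0.swap(prop_lq0);
        } else {
          th[j] = cur;
        }
      }
      ntry[j]++; acc[j] += alpha;
      if (adapt) ls[j] += gamma * (alpha - target);
    }

    // --- survival fixed-effect / year-effect trade-off moves ---
    // (fixed effect up, random effects down along its covariate; the
    // likelihood is exactly invariant, only the eps prior changes)
    for (int j = 0; j < n_sfix; ++j) {
      double delta = std::exp(ls_tilt_s[j]) * norm_rand();
      double alpha = 0.0;
      if (std::fabs(th[j] + delta) < d.B) {
        double dlt = 0.0;
        double sig = th[i_sig_eps];
        const std::vector<double>& x = sxcov[j];
        for (int t = 0; t < T; ++t) {
          dlt += norm_lpdf(th[i_eps + t] - delta * x[t], sig) -
                 norm_lpdf(th[i_eps + t], sig);
        }
        alpha = std::min(1.0, std::exp(dlt));
        if (unif_rand() < alpha) {
          th[j] += delta;
          for (int t = 0; t < T; ++t) {
            th[i_eps + t] -= delta * x[t];
            lp0[t] += delta * x[t];
          }
        }
      }
      if (adapt) ls_tilt_s[j] += gamma * (alpha - target);
    }

    // --- productivity fixed effects: joint adapted block ---
    {
      ba_p.propose(&th[i_pfix], &bprop[0]);
      bool inb = true;
      for (int j = 0; j < n_pfix; ++j) {
        if (std::fabs(bprop[j]) >= d.B) inb = false;
      }
      double alpha = 0.0;
      if (inb) {
        std::vector<double> save(th.begin() + i_pfix,
                                 th.begin() + i_pfix + n_pfix);
        for (int j = 0; j < n_pfix; ++j) th[i_pfix + j] = bprop[j];
        prod_lq0(d, &th[i_pfix], prop_lq0);
        double prop_pll = prod_ll(d, prop_lq0, &th[i_eta]);
        alpha = std::min(1.0, std::exp(prop_pll - pll));
        if (unif_rand() < alpha) {
          pll = prop_pll;
          lq0.swap(prop_lq0);
        } else {
          for (int j = 0; j < n_pfix; ++j) th[i_pfix + j] = save[j];
        }
      }
      if (adapt) {
        ba_p.lscale += gamma * (alpha - btarget);
        ba_p.update(&th[i_pfix]);
        if ((it + 1) % 100 == 0) ba_p.refresh_chol();
      }
    }

    // --- sigma_eta ---
    {
      int j = i_sig_eta;
      double cur = th[j];
      double prop = cur + std::exp(ls[j]) * norm_rand();
      double alpha = 0.0;
      if (prop > 0) {
        double dlt = half_cauchy_lpdf(prop, d.scale) -
                     half_cauchy_lpdf(cur, d.scale) +
                     re_prior(&th[i_eta], R, prop) -
                     re_prior(&th[i_eta], R, cur);
        alpha = std::min(1.0, std::exp(dlt));
        if (unif_rand() < alpha) th[j] = prop;
      }
      ntry[j]++; acc[j] += alpha;
      if (adapt) ls[j] += gamma * (alpha - target);
    }

    // --- productivity fixed-effect / year-effect trade-off moves ---
    for (int j = 0; j < n_pfix; ++j) {
      double delta = std::exp(ls_tilt_p[j]) * norm_rand();
      double alpha = 0.0;
      if (std::fabs(th[i_pfix + j] + delta) < d.B) {
        double dlt = 0.0;
        double sig = th[i_sig_eta];
        const std::vector<double>& x = pxcov[j];
        for (int i = 0; i < R; ++i) {
          dlt += norm_lpdf(th[i_eta + i] - delta * x[i], sig) -
                 norm_lpdf(th[i_eta + i], sig);
        }
        alpha = std::min(1.0, std::exp(dlt));
        if (unif_rand() < alpha) {
          th[i_pfix + j] += delta;
          for (int i = 0; i < R; ++i) {
            th[i_eta + i] -= delta * x[i];
            lq0[i] += delta * x[i];
          }
        }
      }
      if (adapt) ls_tilt_p[j] += gamma * (alpha - target);
    }

    // --- eta: single-site vectorised ---
    for (int i = 0; i < R; ++i) {
      int j = i_eta + i;
      double cur = th[j];
      double prop = cur + std::exp(ls[j]) * norm_rand();
      double cur_ll = prod_ll_trans(d, i, lq0[i] + cur);
      double prop_ll = prod_ll_trans(d, i, lq0[i] + prop);
      double dlt = prop_ll - cur_ll +
                   norm_lpdf(prop, th[i_sig_eta]) -
                   norm_lpdf(cur, th[i_sig_eta]);
      double alpha = std::min(1.0, std::exp(dlt));
      if (unif_rand() < alpha) {
        th[j] = prop;
        pll += prop_ll - cur_ll;
      }
      ntry[j]++; acc[j] += alpha;
      if (adapt) ls[j] += gamma * (alpha - target);
    }

    if (it >= n_warmup && (it - n_warmup) % thin == 0 && kept < n_keep) {
      for (int p = 0; p < n_par; ++p) draws(kept, p) = th[p];
      ++kept;
    }
  }

  NumericVector accept(n_par);
  for (int p = 0; p < n_par; ++p) {
    accept[p] = ntry[p] > 0 ? acc[p] / ntry[p] : NA_REAL;
  }
  return List::create(_["draws"] = draws, _["accept"] = accept);
}
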