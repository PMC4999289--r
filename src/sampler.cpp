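// Adaptive Metropolis-within-Gibbs sampler for the binomial-logit NMA model.
//
// Parameterisation: per-study baseline log-odds mu_i; per non-baseline arm
// trial-specific log-OR delta_ik (RE) or the deterministic contrast
// d[t] - d[base] (FE); basic effects d_k versus treatment 1 (d_1 = 0);
// between-study SD sigma with U(0, upper) prior; common interaction beta.
// Multi-arm RE prior: MVN with per-arm variance sigma^2 and pairwise
// covariance sigma^2/2, evaluated in closed form.
//
// Proposals are component-wise Gaussian random walks whose log step sizes
// adapt toward 44% acceptance during burn-in (diminishing adaptation),
// then freeze. Uses R's RNG so set.seed() on the R side makes runs
// reproducible per chain.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double softplus(double x) {
  // log(1 + exp(x)), stable
  if (x > 0) return x + std::log1p(std::exp(-x));
  return std::log1p(std::exp(x));
}

struct NmaData {
  int S, K, A, ND;
  std::vector<int> study, treat, base, didx; // per arm; didx = -1 on baseline arms
  std::vector<int> w;                        // interaction indicator per arm
  std::vector<double> r, n;
  std::vector<std::vector<int>> study_arms;  // arms per study
  std::vector<std::vector<int>> study_nb;    // non-baseline arms per study
  std::vector<std::vector<int>> treat_arms;  // non-baseline arms whose contrast involves d_k
  std::vector<std::vector<int>> treat_studies; // studies whose delta-prior mean involves d_k
  int mode;        // 0 none, 1 covariate, 2 baseline risk
  int re;          // 1 RE, 0 FE
  int hier;        // 1 = exchangeable baselines mu_i ~ N(b_mean, b_sd^2)
  std::vector<double> x;  // per study (mode 1)
  double m_center;        // mode 2
  double pm, psd, sd_up, bpm, bpsd, bsd_up;
};

struct NmaState {
  std::vector<double> mu, d, delta;
  double sigma, beta;
  double b_mean, b_sd;   // baseline hyperparameters (hier only)
};

static inline double xval(const NmaData &dat, const NmaState &st, int s) {
  if (dat.mode == 1) return dat.x[s];
  if (dat.mode == 2) return st.mu[s] - dat.m_center;
  return 0.0;
}

static inline double eta_arm(const NmaData &dat, const NmaState &st, int a) {
  int s = dat.study[a];
  double e = st.mu[s];
  if (dat.didx[a] >= 0) {
    e += dat.re ? st.delta[dat.didx[a]]
                : (st.d[dat.treat[a]] - st.d[dat.base[a]]);
  }
  if (dat.mode != 0 && dat.w[a] != 0) e += st.beta * xval(dat, st, s) * dat.w[a];
  return e;
}

static inline double loglik_arm(const NmaData &dat, const NmaState &st, int a) {
  double e = eta_arm(dat, st, a);
  return dat.r[a] * e - dat.n[a] * softplus(e);
}

// closed-form MVN log density of study s's delta vector (RE only)
static double delta_logprior(const NmaData &dat, const NmaState &st, int s) {
  const std::vector<int> &nb = dat.study_nb[s];
  int m = (int)nb.size();
  double s2 = st.sigma * st.sigma;
  double se = 0.0, se2 = 0.0;
  for (int a : nb) {
    double e = st.delta[dat.didx[a]] - (st.d[dat.treat[a]] - st.d[dat.base[a]]);
    se += e; se2 += e * e;
  }
  double qf = (2.0 / s2) * (se2 - se * se / (m + 1));
  double logdet = m * std::log(s2 / 2.0) + std::log((double)(m + 1));
  return -0.5 * (m * std::log(2.0 * M_PI) + logdet + qf);
}

static inline double dnorm_log(double v, double mean, double sd) {
  double z = (v - mean) / sd;
  return -0.5 * z * z - std::log(sd) - 0.5 * std::log(2.0 * M_PI);
}

class Stepper {
public:
  std::vector<double> ls;   // log step sizes
  std::vector<long> acc, tries;
  bool adapting;
  long iter;
  Stepper(int n, double init) : ls(n, std::log(init)), acc(n, 0), tries(n, 0),
                                adapting(true), iter(1) {}
  double step(int j) { return std::exp(ls[j]); }
  void update(int j, double alpha, bool accepted) {
    tries[j]++; if (accepted) acc[j]++;
    if (adapting) {
      double gain = 1.0 / std::sqrt((double)iter);
      if (gain > 0.05) gain = 0.05;
      ls[j] += gain * (alpha - 0.44);
      if (ls[j] < -8) ls[j] = -8;
      if (ls[j] > 3) ls[j] = 3;
    }
  }
};

static bool mh_accept(double dll, double &alpha) {
  if (!std::isfinite(dll)) { alpha = 0.0; return false; }
  alpha = dll >= 0 ? 1.0 : std::exp(dll);
  return unif_rand() < alpha;
}

// [[Rcpp::export(name = ".nma_mcmc_chain")]]
List nma_mcmc_chain(List data, List init, int burn_in, int samples, int thin) {
  NmaData dat;
  IntegerVector study = data["study"], treat = data["treat"], base = data["base"],
                didx = data["didx"], wv = data["w"];
  NumericVector rv = data["r"], nv = data["n"];
  dat.S = as<int>(data["S"]); dat.K = as<int>(data["K"]);
  dat.A = study.size();
  dat.mode = as<int>(data["mode"]); dat.re = as<int>(data["re"]);
  dat.hier = as<int>(data["hier"]); dat.bsd_up = as<double>(data["bsd_up"]);
  dat.m_center = as<double>(data["m_center"]);
  NumericVector xv = data["x"];
  dat.x.assign(xv.begin(), xv.end());
  dat.pm = as<double>(data["pm"]); dat.psd = as<double>(data["psd"]);
  dat.sd_up = as<double>(data["sd_up"]);
  dat.bpm = as<double>(data["bpm"]); dat.bpsd = as<double>(data["bpsd"]);

  dat.study.assign(study.begin(), study.end());
  dat.treat.assign(treat.begin(), treat.end());
  dat.base.assign(base.begin(), base.end());
  dat.didx.assign(didx.begin(), didx.end());
  dat.w.assign(wv.begin(), wv.end());
  dat.r.assign(rv.begin(), rv.end());
  dat.n.assign(nv.begin(), nv.end());
  dat.ND = 0;
  for (int a = 0; a < dat.A; ++a) if (dat.didx[a] >= 0) dat.ND++;

  dat.study_arms.assign(dat.S, {});
  dat.study_nb.assign(dat.S, {});
  dat.treat_arms.assign(dat.K, {});
  dat.treat_studies.assign(dat.K, {});
  for (int a = 0; a < dat.A; ++a) {
    dat.study_arms[dat.study[a]].push_back(a);
    if (dat.didx[a] >= 0) {
      dat.study_nb[dat.study[a]].push_back(a);
      dat.treat_arms[dat.treat[a]].push_back(a);
      dat.treat_arms[dat.base[a]].push_back(a);
    }
  }
  for (int k = 0; k < dat.K; ++k) {
    std::vector<bool> seen(dat.S, false);
    for (int a : dat.treat_arms[k])
      if (!seen[dat.study[a]]) { seen[dat.study[a]] = true; dat.treat_studies[k].push_back(dat.study[a]); }
  }

  NmaState st;
  NumericVector mu0 = init["mu"], d0 = init["d"], delta0 = init["delta"];
  st.mu.assign(mu0.begin(), mu0.end());
  st.d.assign(d0.begin(), d0.end());
  st.delta.assign(delta0.begin(), delta0.end());
  st.sigma = as<double>(init["sigma"]);
  st.beta = as<double>(init["beta"]);
  st.b_mean = as<double>(init["b_mean"]);
  st.b_sd = as<double>(init["b_sd"]);

  // parameter layout for adaptation: mu | delta | d(2..K) | sigma | beta | b_mean | b_sd
  int n_mu = dat.S, n_delta = dat.re ? dat.ND : 0, n_d = dat.K - 1;
  int off_delta = n_mu, off_d = n_mu + n_delta, off_sigma = off_d + n_d,
      off_beta = off_sigma + 1, off_bm = off_beta + 1, off_bs = off_bm + 1;
  Stepper stp(off_bs + 1, 0.5);
  stp.ls[off_sigma] = std::log(0.2);
  stp.ls[off_bs] = std::log(0.2);

  int nkeep = samples / thin;
  // d2..dK, sigma, beta, mu, delta, b_mean, b_sd
  int npar = n_d + 1 + 1 + dat.S + dat.ND + 2;
  NumericMatrix draws(nkeep, npar);
  NumericMatrix pdraws(nkeep, dat.A);

  RNGScope scope;
  int kept = 0;
  long total_iter = (long)burn_in + samples;
  for (long it = 0; it < total_iter; ++it) {
    stp.adapting = it < burn_in;
    stp.iter = it + 1;

    // --- mu updates ---
    double mu_pm = dat.hier ? st.b_mean : dat.pm;
    double mu_psd = dat.hier ? st.b_sd : dat.psd;
    for (int s = 0; s < dat.S; ++s) {
      double old = st.mu[s];
      double cur = dnorm_log(old, mu_pm, mu_psd);
      for (int a : dat.study_arms[s]) cur += loglik_arm(dat, st, a);
      st.mu[s] = old + norm_rand() * stp.step(s);
      double prop = dnorm_log(st.mu[s], mu_pm, mu_psd);
      for (int a : dat.study_arms[s]) prop += loglik_arm(dat, st, a);
      double alpha; bool ok = mh_accept(prop - cur, alpha);
      if (!ok) st.mu[s] = old;
      stp.update(s, alpha, ok);
    }

    // --- baseline hyperparameters (exchangeable baselines) ---
    if (dat.hier) {
      double old = st.b_mean;
      double cur = dnorm_log(old, dat.pm, dat.psd);
      for (int s = 0; s < dat.S; ++s) cur += dnorm_log(st.mu[s], old, st.b_sd);
      double prop_bm = old + norm_rand() * stp.step(off_bm);
      double prop = dnorm_log(prop_bm, dat.pm, dat.psd);
      for (int s = 0; s < dat.S; ++s) prop += dnorm_log(st.mu[s], prop_bm, st.b_sd);
      double alpha; bool ok = mh_accept(prop - cur, alpha);
      if (ok) st.b_mean = prop_bm;
      stp.update(off_bm, alpha, ok);

      double olds = st.b_sd;
      double prop_bs = olds + norm_rand() * stp.step(off_bs);
      alpha = 0.0; ok = false;
      if (prop_bs > 0 && prop_bs < dat.bsd_up) {
        double cur2 = 0.0, prop2 = 0.0;
        for (int s = 0; s < dat.S; ++s) {
          cur2 += dnorm_log(st.mu[s], st.b_mean, olds);
          prop2 += dnorm_log(st.mu[s], st.b_mean, prop_bs);
        }
        ok = mh_accept(prop2 - cur2, alpha);
        if (ok) st.b_sd = prop_bs;
      }
      stp.update(off_bs, alpha, ok);
    }

    // --- delta updates (RE) ---
    if (dat.re) {
      for (int s = 0; s < dat.S; ++s) {
        for (int a : dat.study_nb[s]) {
          int j = dat.didx[a];
          double old = st.delta[j];
          double cur = loglik_arm(dat, st, a) + delta_logprior(dat, st, s);
          st.delta[j] = old + norm_rand() * stp.step(off_delta + j);
          double prop = loglik_arm(dat, st, a) + delta_logprior(dat, st, s);
          double alpha; bool ok = mh_accept(prop - cur, alpha);
          if (!ok) st.delta[j] = old;
          stp.update(off_delta + j, alpha, ok);
        }
      }
    }

    // --- d updates (k = 2..K; index 1..K-1) ---
    for (int k = 1; k < dat.K; ++k) {
      double old = st.d[k];
      double cur = dnorm_log(old, dat.pm, dat.psd);
      if (dat.re) for (int s : dat.treat_studies[k]) cur += delta_logprior(dat, st, s);
      else        for (int a : dat.treat_arms[k])    cur += loglik_arm(dat, st, a);
      st.d[k] = old + norm_rand() * stp.step(off_d + k - 1);
      double prop = dnorm_log(st.d[k], dat.pm, dat.psd);
      if (dat.re) for (int s : dat.treat_studies[k]) prop += delta_logprior(dat, st, s);
      else        for (int a : dat.treat_arms[k])    prop += loglik_arm(dat, st, a);
      double alpha; bool ok = mh_accept(prop - cur, alpha);
      if (!ok) st.d[k] = old;
      stp.update(off_d + k - 1, alpha, ok);
    }

    // --- sigma update (RE) ---
    if (dat.re) {
      double old = st.sigma;
      double prop_sigma = old + norm_rand() * stp.step(off_sigma);
      double alpha = 0.0; bool ok = false;
      if (prop_sigma > 0 && prop_sigma < dat.sd_up) {
        double cur = 0.0, prop = 0.0;
        for (int s = 0; s < dat.S; ++s) cur += delta_logprior(dat, st, s);
        st.sigma = prop_sigma;
        for (int s = 0; s < dat.S; ++s) prop += delta_logprior(dat, st, s);
        ok = mh_accept(prop - cur, alpha);
        if (!ok) st.sigma = old;
      }
      stp.update(off_sigma, alpha, ok);
    }

    // --- beta update ---
    if (dat.mode != 0) {
      double old = st.beta;
      double cur = dnorm_log(old, dat.bpm, dat.bpsd);
      for (int a = 0; a < dat.A; ++a) if (dat.w[a] != 0) cur += loglik_arm(dat, st, a);
      st.beta = old + norm_rand() * stp.step(off_beta);
      double prop = dnorm_log(st.beta, dat.bpm, dat.bpsd);
      for (int a = 0; a < dat.A; ++a) if (dat.w[a] != 0) prop += loglik_arm(dat, st, a);
      double alpha; bool ok = mh_accept(prop - cur, alpha);
      if (!ok) st.beta = old;
      stp.update(off_beta, alpha, ok);
    }

    // --- record ---
    if (it >= burn_in && ((it - burn_in) % thin == 0) && kept < nkeep) {
      int c = 0;
      for (int k = 1; k < dat.K; ++k) draws(kept, c++) = st.d[k];
      draws(kept, c++) = st.sigma;
      draws(kept, c++) = st.beta;
      for (int s = 0; s < dat.S; ++s) draws(kept, c++) = st.mu[s];
      for (int a = 0; a < dat.A; ++a)
        if (dat.didx[a] >= 0)
          draws(kept, c++) = dat.re ? st.delta[dat.didx[a]]
                                    : (st.d[dat.treat[a]] - st.d[dat.base[a]]);
      draws(kept, c++) = st.b_mean;
      draws(kept, c++) = st.b_sd;
      for (int a = 0; a < dat.A; ++a) {
        double e = eta_arm(dat, st, a);
        pdraws(kept, a) = 1.0 / (1.0 + std::exp(-e));
      }
      kept++;
    }
  }

  NumericVector acc_rate(stp.ls.size());
  for (size_t j = 0; j < stp.ls.size(); ++j)
    acc_rate[j] = stp.tries[j] ? (double)stp.acc[j] / stp.tries[j] : NA_REAL;

  return List::create(_["draws"] = draws, _["p"] = pdraws,
                      _["accept"] = acc_rate);
}
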