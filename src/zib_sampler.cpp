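// Adaptive Metropolis-within-Gibbs sampler for the zero-inflated beta
// dyadic regression with focal, multi-membership and (optional) dyad
// random effects.
//
// Likelihood:  y = 0 with probability pi (intercept-only zero part:
// exact Gibbs via beta-binomial conjugacy; with covariates: joint
// random-walk MH on the logistic coefficients); positive y ~
// Beta(mu*phi, (1-mu)*phi), logit(mu) = X beta + a[focal] + m[i] + m[j]
// (+ d[dyad]).
//
// beta is updated as a joint block with a Haario-style adaptive
// multivariate normal proposal (empirical covariance learned during
// warmup, frozen afterwards); phi and the random-effect SDs use
// log-scale random walks; each random effect is a single-site random
// walk over the observations it touches.  All proposal scales adapt
// toward standard acceptance targets during warmup only, so the
// post-warmup chain is a valid fixed-kernel MCMC.  All randomness comes
// from R's RNG: seeding via set.seed() in R makes runs bit-reproducible.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double inv_logit(double x) {
  return 1.0 / (1.0 + std::exp(-x));
}

// log density of Beta(mu*phi, (1-mu)*phi) at y, with log(y) and
// log1p(-y) precomputed once per fit (they dominate the inner loop)
static inline double lbeta_mu_phi_c(double ly, double l1my, double mu,
                                    double phi) {
  double a = mu * phi, b = (1.0 - mu) * phi;
  return R::lgammafn(phi) - R::lgammafn(a) - R::lgammafn(b) +
    (a - 1.0) * ly + (b - 1.0) * l1my;
}

struct ReBlock {
  bool active = false;
  int n = 0;
  std::vector<double> val;           // effect values
  std::vector<double> scale;         // per-node proposal sds
  std::vector<std::vector<int>> obs; // positive-obs indices per node
  double sigma = 0.5;                // population SD
  double sigma_scale = 0.3;          // proposal sd for log sigma
};

class ZibSampler {
public:
  // data
  int NP = 0, N = 0, nz = 0, P = 0, Q = 1;
  NumericMatrix Xp;          // NP x P design of positive rows
  NumericVector yp;          // positive responses
  NumericMatrix Xz;          // N x Q zero-part design (Q>=2 only)
  IntegerVector zvec;        // zero indicators (Q>=2 only)
  bool zi_conjugate = true;
  // parameters
  std::vector<double> beta, gamma_;
  double phi = 5.0;
  ReBlock A, M, D;
  // priors (per-coordinate sds on beta: column scaling is handled in R
  // and folded into these)
  std::vector<double> beta_prior_sd;
  double re_scale = 1.0, phi_rate = 0.1;
  // adaptation state for the beta block
  std::vector<double> beta_mean, beta_cov; // running moments (P, PxP)
  double beta_log_scale = 0.0;
  long beta_adapt_n = 0;
  double phi_scale = 0.3, gamma_scale = 0.3;
  std::vector<double> beta_coord_scale;
  double sweep_scale_a = 0.2, sweep_scale_m = 0.2;
  double rescale_a = 0.2, rescale_m = 0.2, rescale_d = 0.2;
  bool has_intercept = false;
  // cached linear predictor and response logs of positive rows
  std::vector<double> eta, ly, l1my;

  double pos_loglik_obs(int i) const {
    return lbeta_mu_phi_c(ly[i], l1my[i], inv_logit(eta[i]), phi);
  }

  double pos_loglik_at(int i, double eta_i) const {
    return lbeta_mu_phi_c(ly[i], l1my[i], inv_logit(eta_i), phi);
  }

  double pos_loglik_all() const {
    double s = 0;
    for (int i = 0; i < NP; ++i) s += pos_loglik_obs(i);
    return s;
  }

  void rebuild_eta() {
    for (int i = 0; i < NP; ++i) {
      double e = 0;
      for (int j = 0; j < P; ++j) e += Xp(i, j) * beta[j];
      eta[i] = e;
    }
    add_re(A); add_re(M, true); add_re(D);
  }

  void add_re(const ReBlock &B, bool twice = false) {
    if (!B.active) return;
    for (int k = 0; k < B.n; ++k)
      for (int i : B.obs[k]) eta[i] += B.val[k];
    (void)twice; // member obs lists already contain an entry per slot
  }

  // ---- updates -------------------------------------------------------
  void update_beta(bool adapt) {
    // joint proposal: N(0, exp(2*ls) * (Cov + eps I))
    std::vector<double> prop(P), delta(P);
    double ls = beta_log_scale;
    // Cholesky of adapted covariance (or identity early on)
    std::vector<double> L(P * P, 0.0);
    bool use_cov = beta_adapt_n > 2 * P;
    if (use_cov) {
      std::vector<double> C(beta_cov);
      for (int j = 0; j < P; ++j) C[j * P + j] += 1e-6;
      // Cholesky
      for (int c = 0; c < P; ++c) {
        double s = C[c * P + c];
        for (int k = 0; k < c; ++k) s -= L[c * P + k] * L[c * P + k];
        if (s <= 0) { use_cov = false; break; }
        L[c * P + c] = std::sqrt(s);
        for (int r = c + 1; r < P; ++r) {
          double t = C[r * P + c];
          for (int k = 0; k < c; ++k) t -= L[r * P + k] * L[c * P + k];
          L[r * P + c] = t / L[c * P + c];
        }
      }
    }
    std::vector<double> zdraw(P);
    for (int j = 0; j < P; ++j) zdraw[j] = R::norm_rand();
    double sc = std::exp(ls) * 2.38 / std::sqrt((double)P);
    for (int j = 0; j < P; ++j) {
      double step = 0;
      if (use_cov) {
        for (int k = 0; k <= j; ++k) step += L[j * P + k] * zdraw[k];
      } else {
        step = zdraw[j] * 0.1;
      }
      delta[j] = sc * step;
      prop[j] = beta[j] + delta[j];
    }
    // delta eta
    double ll_old = 0, ll_new = 0;
    std::vector<double> eta_new(NP);
    for (int i = 0; i < NP; ++i) {
      double de = 0;
      for (int j = 0; j < P; ++j) de += Xp(i, j) * delta[j];
      eta_new[i] = eta[i] + de;
      ll_old += pos_loglik_obs(i);
      ll_new += pos_loglik_at(i, eta_new[i]);
    }
    double lp_old = 0, lp_new = 0;
    for (int j = 0; j < P; ++j) {
      lp_old += R::dnorm(beta[j], 0.0, beta_prior_sd[j], 1);
      lp_new += R::dnorm(prop[j], 0.0, beta_prior_sd[j], 1);
    }
    bool acc = std::log(R::unif_rand()) < (ll_new + lp_new - ll_old - lp_old);
    if (acc) { beta = prop; eta = eta_new; }
    if (adapt) {
      beta_log_scale += 0.1 * ((acc ? 1.0 : 0.0) - 0.234);
      // running mean/covariance of beta draws
      ++beta_adapt_n;
      double w = 1.0 / beta_adapt_n;
      std::vector<double> old_mean(beta_mean);
      for (int j = 0; j < P; ++j)
        beta_mean[j] += w * (beta[j] - beta_mean[j]);
      if (beta_adapt_n > 1) {
        for (int r = 0; r < P; ++r)
          for (int c = 0; c < P; ++c) {
            double upd = (beta[r] - old_mean[r]) * (beta[c] - beta_mean[c]);
            beta_cov[r * P + c] +=
              w * (upd - beta_cov[r * P + c]);
          }
      }
    }
  }

  // Robust coordinate-wise random walk on beta with per-coordinate
  // adaptive scales; complements the joint block (which can learn a
  // degenerate covariance if adaptation starts far from the mode).
  void update_beta_coord(bool adapt) {
    for (int j = 0; j < P; ++j) {
      double dj = beta_coord_scale[j] * R::norm_rand();
      double ll_old = 0, ll_new = 0;
      for (int i = 0; i < NP; ++i) {
        double x = Xp(i, j);
        if (x == 0.0) continue;
        ll_old += pos_loglik_obs(i);
        ll_new += pos_loglik_at(i, eta[i] + x * dj);
      }
      double lr = ll_new - ll_old +
        R::dnorm(beta[j] + dj, 0.0, beta_prior_sd[j], 1) -
        R::dnorm(beta[j], 0.0, beta_prior_sd[j], 1);
      bool acc = std::log(R::unif_rand()) < lr;
      if (acc) {
        for (int i = 0; i < NP; ++i) eta[i] += Xp(i, j) * dj;
        beta[j] += dj;
      }
      if (adapt) beta_coord_scale[j] *=
        std::exp(0.1 * ((acc ? 1.0 : 0.0) - 0.44));
    }
  }

  void update_phi(bool adapt) {
    double lphi = std::log(phi);
    double prop = std::exp(lphi + phi_scale * R::norm_rand());
    double ll_old = pos_loglik_all();
    double keep = phi;
    phi = prop;
    double ll_new = pos_loglik_all();
    phi = keep;
    double lr = ll_new - ll_old - phi_rate * (prop - phi) +
      std::log(prop) - std::log(phi); // Exp prior + log-scale Jacobian
    bool acc = std::log(R::unif_rand()) < lr;
    if (acc) phi = prop;
    if (adapt) phi_scale *= std::exp(0.1 * ((acc ? 1.0 : 0.0) - 0.44));
  }

  void update_re(ReBlock &B, bool adapt) {
    if (!B.active) return;
    for (int k = 0; k < B.n; ++k) {
      double prop = B.val[k] + B.scale[k] * R::norm_rand();
      double dval = prop - B.val[k];
      double ll_old = 0, ll_new = 0;
      for (int i : B.obs[k]) {
        ll_old += pos_loglik_obs(i);
        ll_new += pos_loglik_at(i, eta[i] + dval);
      }
      double lr = ll_new - ll_old +
        R::dnorm(prop, 0.0, B.sigma, 1) -
        R::dnorm(B.val[k], 0.0, B.sigma, 1);
      bool acc = std::log(R::unif_rand()) < lr;
      if (acc) {
        for (int i : B.obs[k]) eta[i] += dval;
        B.val[k] = prop;
      }
      if (adapt) B.scale[k] *= std::exp(0.1 * ((acc ? 1.0 : 0.0) - 0.44));
    }
    // population SD: log-scale RW, half-Normal(re_scale) prior
    double ls = std::log(B.sigma);
    double prop = std::exp(ls + B.sigma_scale * R::norm_rand());
    double lr = 0;
    for (int k = 0; k < B.n; ++k) {
      lr += R::dnorm(B.val[k], 0.0, prop, 1) -
        R::dnorm(B.val[k], 0.0, B.sigma, 1);
    }
    lr += R::dnorm(prop, 0.0, re_scale, 1) -
      R::dnorm(B.sigma, 0.0, re_scale, 1);
    lr += std::log(prop) - std::log(B.sigma);
    bool acc = std::log(R::unif_rand()) < lr;
    if (acc) B.sigma = prop;
    if (adapt) B.sigma_scale *= std::exp(0.1 * ((acc ? 1.0 : 0.0) - 0.44));
  }

  // Scale move: multiply a block's SD and all its effects by a common
  // factor c = exp(delta).  Counters the funnel between the SD and the
  // effect magnitudes.
  void update_rescale(ReBlock &B, double &scale, bool adapt) {
    if (!B.active) return;
    double delta = scale * R::norm_rand();
    double c = std::exp(delta);
    double ll_old = pos_loglik_all();
    std::vector<double> eta_keep(eta);
    for (int k = 0; k < B.n; ++k) {
      double dval = B.val[k] * (c - 1.0);
      for (int i : B.obs[k]) eta[i] += dval;
    }
    double ll_new = pos_loglik_all();
    // log-ratio: dloglik + dprior(sigma) + (n+1)*delta (Jacobian)
    // - n*delta (effect priors under the rescaled SD) = ... + delta
    double lr = ll_new - ll_old + delta +
      R::dnorm(c * B.sigma, 0.0, re_scale, 1) -
      R::dnorm(B.sigma, 0.0, re_scale, 1);
    bool acc = std::log(R::unif_rand()) < lr;
    if (acc) {
      B.sigma *= c;
      for (int k = 0; k < B.n; ++k) B.val[k] *= c;
    } else {
      eta = eta_keep;
    }
    if (adapt) scale *= std::exp(0.1 * ((acc ? 1.0 : 0.0) - 0.44));
  }

  // Translation move: shift the intercept by delta and every effect of
  // block B by -delta/slots, leaving eta (hence the likelihood)
  // unchanged; only the priors enter the acceptance ratio.  This
  // decorrelates the intercept from the random-effect means.
  void update_sweep(ReBlock &B, double slots, double &scale, bool adapt) {
    if (!B.active || !has_intercept) return;
    double delta = scale * R::norm_rand();
    double lr = R::dnorm(beta[0] + delta, 0.0, beta_prior_sd[0], 1) -
      R::dnorm(beta[0], 0.0, beta_prior_sd[0], 1);
    for (int k = 0; k < B.n; ++k) {
      lr += R::dnorm(B.val[k] - delta / slots, 0.0, B.sigma, 1) -
        R::dnorm(B.val[k], 0.0, B.sigma, 1);
    }
    bool acc = std::log(R::unif_rand()) < lr;
    if (acc) {
      beta[0] += delta;
      for (int k = 0; k < B.n; ++k) B.val[k] -= delta / slots;
    }
    if (adapt) scale *= std::exp(0.1 * ((acc ? 1.0 : 0.0) - 0.44));
  }

  void update_gamma(bool adapt) {
    if (zi_conjugate) {
      // Logistic(0,1) prior on the intercept = uniform on pi
      double pi = R::rbeta(1.0 + nz, 1.0 + (N - nz));
      pi = std::min(std::max(pi, 1e-12), 1.0 - 1e-12);
      gamma_[0] = std::log(pi / (1.0 - pi));
      return;
    }
    std::vector<double> prop(Q);
    for (int q = 0; q < Q; ++q)
      prop[q] = gamma_[q] + gamma_scale * R::norm_rand();
    double ll_old = 0, ll_new = 0;
    for (int i = 0; i < N; ++i) {
      double e0 = 0, e1 = 0;
      for (int q = 0; q < Q; ++q) {
        e0 += Xz(i, q) * gamma_[q];
        e1 += Xz(i, q) * prop[q];
      }
      double p0 = inv_logit(e0), p1 = inv_logit(e1);
      if (zvec[i]) { ll_old += std::log(p0); ll_new += std::log(p1); }
      else { ll_old += std::log1p(-p0); ll_new += std::log1p(-p1); }
    }
    double lp_old = 0, lp_new = 0;
    for (int q = 0; q < Q; ++q) {
      lp_old += R::dlogis(gamma_[q], 0.0, 1.0, 1);
      lp_new += R::dlogis(prop[q], 0.0, 1.0, 1);
    }
    bool acc = std::log(R::unif_rand()) <
      (ll_new + lp_new - ll_old - lp_old);
    if (acc) gamma_ = prop;
    if (adapt) gamma_scale *= std::exp(0.1 * ((acc ? 1.0 : 0.0) - 0.234));
  }
};

static void init_block(ReBlock &B, int n, const IntegerVector &idx1,
                       const IntegerVector &idx2, int NP) {
  B.active = n > 0;
  if (!B.active) return;
  B.n = n;
  B.val.assign(n, 0.0);
  B.scale.assign(n, 0.3);
  B.obs.assign(n, {});
  for (int i = 0; i < NP; ++i) {
    if (idx1.size() > 0) B.obs[idx1[i] - 1].push_back(i);
    if (idx2.size() > 0) B.obs[idx2[i] - 1].push_back(i);
  }
}

// [[Rcpp::export(name = ".zib_mcmc_chain")]]
NumericMatrix zib_mcmc_chain(NumericVector yp, NumericMatrix Xp,
                             IntegerVector fp, IntegerVector m1p,
                             IntegerVector m2p, IntegerVector dp,
                             int NF, int NB, int ND,
                             int N, int nz,
                             NumericMatrix Xz, IntegerVector zvec,
                             List priors, NumericVector beta_init,
                             NumericVector beta_prior_sd,
                             int n_iter, int n_warmup,
                             bool has_intercept) {
  ZibSampler S;
  S.NP = yp.size(); S.P = Xp.ncol(); S.N = N; S.nz = nz;
  S.yp = yp; S.Xp = Xp;
  S.Q = Xz.ncol();
  S.Xz = Xz; S.zvec = zvec;
  S.zi_conjugate = (S.Q == 1);
  S.re_scale = as<double>(priors["re_sd_scale"]);
  S.phi_rate = as<double>(priors["phi_rate"]);
  S.beta_prior_sd.assign(beta_prior_sd.begin(), beta_prior_sd.end());
  S.beta.assign(beta_init.begin(), beta_init.end());
  S.beta_coord_scale.assign(S.P, 0.1);
  S.gamma_.assign(S.Q, 0.0);
  double pi0 = (nz + 1.0) / (N + 2.0);
  S.gamma_[0] = std::log(pi0 / (1 - pi0));
  S.has_intercept = has_intercept;
  S.beta_mean.assign(S.P, 0.0);
  S.beta_cov.assign(S.P * S.P, 0.0);
  init_block(S.A, NF, fp, IntegerVector(0), S.NP);
  init_block(S.M, NB, m1p, m2p, S.NP);
  init_block(S.D, ND, dp, IntegerVector(0), S.NP);
  S.eta.assign(S.NP, 0.0);
  S.ly.resize(S.NP);
  S.l1my.resize(S.NP);
  for (int i = 0; i < S.NP; ++i) {
    S.ly[i] = std::log(yp[i]);
    S.l1my[i] = std::log1p(-yp[i]);
  }
  S.rebuild_eta();

  bool has_pos = S.NP > 0;
  int n_keep = n_iter - n_warmup;
  int npar = S.P + S.Q + 1 + (S.A.active ? S.A.n + 1 : 0) +
    (S.M.active ? S.M.n + 1 : 0) + (S.D.active ? S.D.n + 1 : 0);
  NumericMatrix out(n_keep, npar);
  for (int it = 0; it < n_iter; ++it) {
    bool adapt = it < n_warmup;
    S.update_gamma(adapt);
    if (has_pos) {
      S.update_beta(adapt);
      S.update_beta_coord(adapt);
      S.update_phi(adapt);
      S.update_re(S.A, adapt);
      S.update_re(S.M, adapt);
      S.update_re(S.D, adapt);
      S.update_sweep(S.A, 1.0, S.sweep_scale_a, adapt);
      S.update_sweep(S.M, 2.0, S.sweep_scale_m, adapt);
      S.update_rescale(S.A, S.rescale_a, adapt);
      S.update_rescale(S.M, S.rescale_m, adapt);
      S.update_rescale(S.D, S.rescale_d, adapt);
    }
    if (it >= n_warmup) {
      int c = 0, r = it - n_warmup;
      for (int j = 0; j < S.P; ++j) out(r, c++) = S.beta[j];
      for (int q = 0; q < S.Q; ++q) out(r, c++) = S.gamma_[q];
      out(r, c++) = S.phi;
      if (S.A.active) {
        out(r, c++) = S.A.sigma;
        for (int k = 0; k < S.A.n; ++k) out(r, c++) = S.A.val[k];
      }
      if (S.M.active) {
        out(r, c++) = S.M.sigma;
        for (int k = 0; k < S.M.n; ++k) out(r, c++) = S.M.val[k];
      }
      if (S.D.active) {
        out(r, c++) = S.D.sigma;
        for (int k = 0; k < S.D.n; ++k) out(r, c++) = S.D.val[k];
      }
    }
  }
  return out;
}
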