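// Sequential likelihoods, generative agents, and the hierarchical sampler
// for the four IGT reinforcement-learning models.
//
// Model ids: 0 = pvl_delta, 1 = pvl_decay, 2 = vpp, 3 = orl.
// Parameter layouts (natural scale):
//   pvl_*: alpha, lam, A, c
//   vpp:   alpha, lam, A, c, K, ep_p, ep_n, w
//   orl:   A_rew, A_pun, K_prime, beta_F, beta_P
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const int N_DECKS = 4;

struct LatentState {
  double E[N_DECKS];   // expectancy (PVL, VPP)
  double P[N_DECKS];   // perseverance (VPP)
  double EV[N_DECKS];  // expected value (ORL)
  double EF[N_DECKS];  // expected frequency (ORL)
  double PS[N_DECKS];  // perseverance (ORL)
  void reset() {
    for (int j = 0; j < N_DECKS; ++j) E[j] = P[j] = EV[j] = EF[j] = PS[j] = 0.0;
  }
};

static inline double prospect_u(double x, double alpha, double lam) {
  return x >= 0.0 ? std::pow(x, alpha) : -lam * std::pow(-x, alpha);
}

static inline double sgn(double x) { return x > 0.0 ? 1.0 : (x < 0.0 ? -1.0 : 0.0); }

// derived per-session constants: softmax sensitivity and ORL decay
static inline void derived_consts(int model, const double* p, double& sens,
                                  double& orl_K) {
  sens = model == 3 ? 1.0 : std::pow(3.0, p[3]) - 1.0;
  orl_K = model == 3 ? std::pow(3.0, p[2]) - 1.0 : 0.0;
}

// deck values implied by the current latent state
static inline void state_values(int model, const double* p, const LatentState& s,
                                double* V) {
  switch (model) {
  case 0: case 1:
    for (int j = 0; j < N_DECKS; ++j) V[j] = s.E[j];
    break;
  case 2: {
    double w = p[7];
    for (int j = 0; j < N_DECKS; ++j) V[j] = w * s.E[j] + (1.0 - w) * s.P[j];
    break;
  }
  default:
    for (int j = 0; j < N_DECKS; ++j) V[j] = s.EV[j] + p[3] * s.EF[j] + p[4] * s.PS[j];
  }
}

// log choice probabilities via a max-stabilised log-softmax
static inline void log_softmax(const double* V, double sens, double* logp) {
  double z[N_DECKS], m = -INFINITY;
  for (int j = 0; j < N_DECKS; ++j) { z[j] = sens * V[j]; if (z[j] > m) m = z[j]; }
  double lse = 0.0;
  for (int j = 0; j < N_DECKS; ++j) lse += std::exp(z[j] - m);
  lse = m + std::log(lse);
  for (int j = 0; j < N_DECKS; ++j) logp[j] = z[j] - lse;
}

// one learning step after observing scaled net outcome x on chosen deck c
static inline void state_update(int model, const double* p, LatentState& s,
                                int c, double x, int orl_same_rate,
                                double orl_K) {
  switch (model) {
  case 0: {
    double u = prospect_u(x, p[0], p[1]);
    s.E[c] += p[2] * (u - s.E[c]);
    break;
  }
  case 1: {
    double u = prospect_u(x, p[0], p[1]);
    for (int j = 0; j < N_DECKS; ++j) s.E[j] *= p[2];
    s.E[c] += u;
    break;
  }
  case 2: {
    double u = prospect_u(x, p[0], p[1]);
    s.E[c] += p[2] * (u - s.E[c]);
    for (int j = 0; j < N_DECKS; ++j) s.P[j] *= p[4];
    s.P[c] += (x >= 0.0) ? p[5] : p[6];
    break;
  }
  default: {
    double A_ch  = (x >= 0.0) ? p[0] : p[1];          // valence-matched rate
    double A_fic = orl_same_rate ? A_ch : ((x >= 0.0) ? p[1] : p[0]);
    double sg = sgn(x);
    s.EV[c] += A_ch * (x - s.EV[c]);
    double ef_ch = s.EF[c] + A_ch * (sg - s.EF[c]);
    for (int j = 0; j < N_DECKS; ++j)
      if (j != c) s.EF[j] += A_fic * (-sg / 3.0 - s.EF[j]);
    s.EF[c] = ef_ch;
    for (int j = 0; j < N_DECKS; ++j)
      s.PS[j] = (j == c ? 1.0 : s.PS[j]) / (1.0 + orl_K);
  }
  }
}

// per-trial log probability of the observed choices (choices are 1-based)
static void session_logp(int model, const double* p, const int* choices,
                         const double* x, int n, int orl_same_rate, double* out) {
  LatentState s; s.reset();
  double V[N_DECKS], logp[N_DECKS], sens, orl_K;
  derived_consts(model, p, sens, orl_K);
  for (int t = 0; t < n; ++t) {
    int c = choices[t] - 1;
    state_values(model, p, s, V);
    log_softmax(V, sens, logp);
    out[t] = logp[c];
    state_update(model, p, s, c, x[t], orl_same_rate, orl_K);
  }
}

static double session_loglik_total(int model, const double* p, const int* choices,
                                   const double* x, int n, int orl_same_rate) {
  LatentState s; s.reset();
  double V[N_DECKS], logp[N_DECKS], sens, orl_K, tot = 0.0;
  derived_consts(model, p, sens, orl_K);
  for (int t = 0; t < n; ++t) {
    int c = choices[t] - 1;
    state_values(model, p, s, V);
    log_softmax(V, sens, logp);
    tot += logp[c];
    state_update(model, p, s, c, x[t], orl_same_rate, orl_K);
  }
  return tot;
}

// [[Rcpp::export]]
NumericVector cpp_session_logp(int model, NumericVector pars, IntegerVector choices,
                               NumericVector x, int orl_same_rate) {
  int n = choices.size();
  NumericVector out(n);
  session_logp(model, pars.begin(), choices.begin(), x.begin(), n, orl_same_rate,
               out.begin());
  return out;
}

// Simulate an agent against precomputed per-deck outcome schedules.
// rewards/losses: n_trials x 4 matrices; row k = outcome of the k-th draw
// from that deck. Choices are sampled with R's RNG so set.seed() governs them.
// [[Rcpp::export]]
List cpp_simulate_agent(int model, NumericVector pars, NumericMatrix rewards,
                        NumericMatrix losses, int n_trials, double scale,
                        int orl_same_rate) {
  LatentState s; s.reset();
  double V[N_DECKS], logp[N_DECKS], sens, orl_K;
  derived_consts(model, pars.begin(), sens, orl_K);
  IntegerVector choice(n_trials);
  NumericVector rew(n_trials), los(n_trials);
  int draws_from[N_DECKS] = {0, 0, 0, 0};
  RNGScope scope;
  for (int t = 0; t < n_trials; ++t) {
    state_values(model, pars.begin(), s, V);
    log_softmax(V, sens, logp);
    double u = unif_rand(), cum = 0.0;
    int c = N_DECKS - 1;
    for (int j = 0; j < N_DECKS; ++j) {
      cum += std::exp(logp[j]);
      if (u <= cum) { c = j; break; }
    }
    int k = draws_from[c]++;
    double r = rewards(k, c), l = losses(k, c), net = r + l;
    choice[t] = c + 1; rew[t] = r; los[t] = l;
    state_update(model, pars.begin(), s, c, net / scale, orl_same_rate, orl_K);
  }
  return List::create(_["deck"] = choice, _["reward"] = rew, _["loss"] = los);
}

// ---------------------------------------------------------------------------
// Hierarchical sampler: non-centered parameterization on the unconstrained
// scale. theta_u[i, p] = mu[p] + sigma[p] * z[i, p]; natural value is
// U[p] * Phi(theta_u) for bounded parameters (link_U > 0) or theta_u itself
// for unbounded ones (link_U == 0). Adaptive random-walk Metropolis within
// Gibbs; proposal scales adapted in batches during warmup only.
// ---------------------------------------------------------------------------

static inline double to_natural(double u, double U) {
  return U > 0.0 ? U * R::pnorm(u, 0.0, 1.0, 1, 0) : u;
}

struct Cohort {
  int model, n_subj, orl_same_rate;
  std::vector<const int*> choices;
  std::vector<const double*> x;
  std::vector<int> n;
  double subj_loglik(const double* pars, int i) const {
    return session_loglik_total(model, pars, choices[i], x[i], n[i], orl_same_rate);
  }
};

// One MCMC chain. choices/x: n_subj x max_n matrices (row-padded), n_per gives
// each subject's trial count. Returns kept draws of mu, sigma, theta (natural),
// pointwise log-likelihoods, and acceptance diagnostics.
// [[Rcpp::export]]
List cpp_fit_chain(int model, IntegerMatrix choices, NumericMatrix x,
                   IntegerVector n_per, NumericVector link_U,
                   NumericVector prior_mu_sd, NumericVector prior_sigma_sd,
                   int n_warmup, int n_keep, int thin, int orl_same_rate) {
  const int n_subj = choices.nrow();
  const int P = link_U.size();
  RNGScope scope;

  // row-major copies so each subject's trials are contiguous
  std::vector<std::vector<int>> ch(n_subj);
  std::vector<std::vector<double>> xx(n_subj);
  Cohort co; co.model = model; co.n_subj = n_subj; co.orl_same_rate = orl_same_rate;
  int total_points = 0;
  for (int i = 0; i < n_subj; ++i) {
    int ni = n_per[i];
    ch[i].resize(ni); xx[i].resize(ni);
    for (int t = 0; t < ni; ++t) { ch[i][t] = choices(i, t); xx[i][t] = x(i, t); }
    co.choices.push_back(ch[i].data());
    co.x.push_back(xx[i].data());
    co.n.push_back(ni);
    total_points += ni;
  }

  // state
  std::vector<double> mu(P), sigma(P), z(n_subj * P), th(n_subj * P), ll(n_subj);
  for (int p = 0; p < P; ++p) {
    mu[p] = 0.5 * norm_rand();
    sigma[p] = 0.2 + 0.5 * std::fabs(norm_rand());
  }
  for (int k = 0; k < n_subj * P; ++k) z[k] = 0.5 * norm_rand();
  std::vector<double> pars(P);
  for (int i = 0; i < n_subj; ++i) {
    for (int p = 0; p < P; ++p) {
      th[i * P + p] = to_natural(mu[p] + sigma[p] * z[i * P + p], link_U[p]);
    }
    ll[i] = co.subj_loglik(&th[i * P], i);
  }

  // adaptive proposal scales
  std::vector<double> s_z(n_subj * P, 0.5), s_mu(P, 0.3), s_sig(P, 0.3);
  std::vector<double> s_zd(n_subj, 0.5);
  std::vector<double> cov_mean(n_subj * P, 0.0), cov_m2(n_subj * P * P, 0.0);
  std::vector<double> cov_n(n_subj, 0.0), chol_i(n_subj * P * P, 0.0);
  std::vector<int> have_chol(n_subj, 0);
  std::vector<int> acc_z(n_subj * P, 0), try_z(n_subj * P, 0);
  std::vector<int> acc_zd(n_subj, 0), try_zd(n_subj, 0);
  std::vector<int> acc_mu(P, 0), try_mu(P, 0), acc_sig(P, 0), try_sig(P, 0);
  const double target = 0.44;
  long long acc_tot = 0, try_tot = 0;

  NumericMatrix mu_draws(n_keep, P), sigma_draws(n_keep, P);
  NumericMatrix theta_draws(n_keep, n_subj * P);
  NumericMatrix ptw(n_keep, total_points);

  int n_iter = n_warmup + n_keep * thin;
  for (int it = 0; it < n_iter; ++it) {
    bool warm = it < n_warmup;

    // subject-level z updates
    for (int i = 0; i < n_subj; ++i) {
      for (int p = 0; p < P; ++p) {
        int k = i * P + p;
        double z_new = z[k] + s_z[k] * norm_rand();
        double th_old = th[i * P + p];
        th[i * P + p] = to_natural(mu[p] + sigma[p] * z_new, link_U[p]);
        double ll_new = co.subj_loglik(&th[i * P], i);
        double lacc = ll_new - ll[i] + 0.5 * (z[k] * z[k] - z_new * z_new);
        ++try_z[k]; ++try_tot;
        if (std::log(unif_rand()) < lacc) {
          z[k] = z_new; ll[i] = ll_new; ++acc_z[k]; ++acc_tot;
        } else {
          th[i * P + p] = th_old;
        }
      }
    }

    // joint adaptive-Metropolis move over each subject's whole z vector:
    // proposal covariance learned from the subject's own warmup draws, so
    // posteriorly correlated parameter pairs are traversed along their ridge
    {
      std::vector<double> eta(P), z_new(P), th_new(P);
      for (int i = 0; i < n_subj; ++i) {
        for (int p = 0; p < P; ++p) eta[p] = norm_rand();
        double dq = 0.0;
        const double* L = &chol_i[i * P * P];
        for (int p = 0; p < P; ++p) {
          double step_p = 0.0;
          if (have_chol[i]) {
            for (int q = 0; q <= p; ++q) step_p += L[p * P + q] * eta[q];
          } else {
            step_p = eta[p];
          }
          z_new[p] = z[i * P + p] + s_zd[i] * step_p;
          th_new[p] = to_natural(mu[p] + sigma[p] * z_new[p], link_U[p]);
          dq += 0.5 * (z[i * P + p] * z[i * P + p] - z_new[p] * z_new[p]);
        }
        double ll_new = co.subj_loglik(th_new.data(), i);
        ++try_zd[i]; ++try_tot;
        if (std::log(unif_rand()) < ll_new - ll[i] + dq) {
          for (int p = 0; p < P; ++p) {
            z[i * P + p] = z_new[p];
            th[i * P + p] = th_new[p];
          }
          ll[i] = ll_new; ++acc_zd[i]; ++acc_tot;
        }
      }
    }

    // accumulate per-subject z moments (warmup only) for the joint proposal
    if (warm) {
      for (int i = 0; i < n_subj; ++i) {
        cov_n[i] += 1.0;
        double w1 = 1.0 / cov_n[i];
        for (int p = 0; p < P; ++p) {
          double d = z[i * P + p] - cov_mean[i * P + p];
          cov_mean[i * P + p] += w1 * d;
          for (int q = 0; q <= p; ++q) {
            double d2 = z[i * P + q] - cov_mean[i * P + q];
            cov_m2[i * P * P + p * P + q] += d * d2;
          }
        }
      }
      if ((it + 1) % 100 == 0 && it + 1 >= 200) {
        std::vector<double> C(P * P);
        for (int i = 0; i < n_subj; ++i) {
          if (cov_n[i] < 2.0) continue;
          for (int p = 0; p < P; ++p)
            for (int q = 0; q <= p; ++q)
              C[p * P + q] = cov_m2[i * P * P + p * P + q] / (cov_n[i] - 1.0) +
                (p == q ? 1e-4 : 0.0);
          // in-place lower Cholesky; fall back to isotropic on failure
          bool ok = true;
          for (int p = 0; p < P && ok; ++p) {
            for (int q = 0; q <= p; ++q) {
              double sum = C[p * P + q];
              for (int k = 0; k < q; ++k) sum -= C[p * P + k] * C[q * P + k];
              if (p == q) {
                if (sum <= 0.0) { ok = false; break; }
                C[p * P + p] = std::sqrt(sum);
              } else {
                C[p * P + q] = sum / C[q * P + q];
              }
            }
          }
          if (ok) {
            bool fresh = !have_chol[i];
            for (int p = 0; p < P; ++p)
              for (int q = 0; q <= p; ++q)
                chol_i[i * P * P + p * P + q] = C[p * P + q];
            have_chol[i] = 1;
            if (fresh) s_zd[i] = 2.38 / std::sqrt((double)P);
          }
        }
      }
    }

    // group-level interweaving: switch to the centered view (individual
    // unconstrained values fixed), Gibbs-update mu, MH-update sigma, and map
    // back to z. The data likelihood depends only on the fixed individual
    // values, so these moves cost no likelihood evaluations.
    for (int p = 0; p < P; ++p) {
      std::vector<double> tu(n_subj);
      double sum_t = 0.0;
      for (int i = 0; i < n_subj; ++i) {
        tu[i] = mu[p] + sigma[p] * z[i * P + p];
        sum_t += tu[i];
      }
      double prec = n_subj / (sigma[p] * sigma[p]) +
                    1.0 / (prior_mu_sd[p] * prior_mu_sd[p]);
      double mean = (sum_t / (sigma[p] * sigma[p])) / prec;
      mu[p] = mean + norm_rand() / std::sqrt(prec);
      ++try_mu[p]; ++acc_mu[p];

      double ss = 0.0;
      for (int i = 0; i < n_subj; ++i) {
        double d = tu[i] - mu[p];
        ss += d * d;
      }
      // log target for sigma given centered values, on the log scale
      auto ltarget = [&](double lsig) {
        double s2 = std::exp(2.0 * lsig);
        return -n_subj * lsig - 0.5 * ss / s2 -
               0.5 * s2 / (prior_sigma_sd[p] * prior_sigma_sd[p]) + lsig;
      };
      double lsig = std::log(sigma[p]);
      double lsig_new = lsig + s_sig[p] * norm_rand();
      ++try_sig[p]; ++try_tot;
      if (std::log(unif_rand()) < ltarget(lsig_new) - ltarget(lsig)) {
        lsig = lsig_new; ++acc_sig[p]; ++acc_tot;
      }
      sigma[p] = std::exp(lsig);
      for (int i = 0; i < n_subj; ++i) z[i * P + p] = (tu[i] - mu[p]) / sigma[p];
      // natural-scale individual values are unchanged by construction
    }

    // batch adaptation during warmup
    if (warm && (it + 1) % 25 == 0) {
      double step = std::min(0.25, 2.0 / std::sqrt((double)(it + 1)));
      for (int k = 0; k < n_subj * P; ++k) {
        if (try_z[k] > 0) {
          double r = (double)acc_z[k] / try_z[k];
          s_z[k] *= std::exp(step * (r - target));
          acc_z[k] = try_z[k] = 0;
        }
      }
      for (int i = 0; i < n_subj; ++i) {
        if (try_zd[i] > 0) {
          double r = (double)acc_zd[i] / try_zd[i];
          s_zd[i] *= std::exp(step * (r - 0.28));
          acc_zd[i] = try_zd[i] = 0;
        }
      }
      for (int p = 0; p < P; ++p) {
        if (try_mu[p] > 0) {
          s_mu[p] *= std::exp(step * ((double)acc_mu[p] / try_mu[p] - target));
          acc_mu[p] = try_mu[p] = 0;
        }
        if (try_sig[p] > 0) {
          s_sig[p] *= std::exp(step * ((double)acc_sig[p] / try_sig[p] - target));
          acc_sig[p] = try_sig[p] = 0;
        }
      }
    }

    if (!warm && (it - n_warmup + 1) % thin == 0) {
      int d = (it - n_warmup + 1) / thin - 1;
      for (int p = 0; p < P; ++p) { mu_draws(d, p) = mu[p]; sigma_draws(d, p) = sigma[p]; }
      for (int k = 0; k < n_subj * P; ++k) theta_draws(d, k) = th[k];
      int col = 0;
      std::vector<double> tr;
      for (int i = 0; i < n_subj; ++i) {
        tr.resize(co.n[i]);
        session_logp(model, &th[i * P], co.choices[i], co.x[i], co.n[i],
                     orl_same_rate, tr.data());
        for (int t = 0; t < co.n[i]; ++t) ptw(d, col++) = tr[t];
      }
    }
    if (it % 200 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["mu"] = mu_draws, _["sigma"] = sigma_draws,
                      _["theta"] = theta_draws, _["pointwise"] = ptw,
                      _["accept_rate"] = (double)acc_tot / (double)try_tot);
}
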