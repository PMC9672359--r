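// Bayesian F_ST decomposition into locus-specific (alpha) and
// population-specific (beta) effects, fitted by reversible-jump MCMC.
//
// Model: at locus i in population j, F_ST(i,j) = 1/(1+exp(-(alpha_i +
// beta_j))). Writing u_ij = exp(-(alpha_i + beta_j)) = (1-F)/F, the
// alternate-allele count k_ij out of n_ij sampled alleles follows a
// beta-binomial with shape (p_i * u_ij, (1-p_i) * u_ij), where p_i is the
// ancestral allele frequency (uniform prior). alpha_i carries a spike at
// zero: a reversible-jump move toggles its inclusion, with prior odds
// `prior_odds` in favour of the neutral (excluded) model and a N(0,
// alpha_sd_prior) slab, which is also the RJ proposal so proposal and
// slab densities cancel. beta_j ~ N(beta_prior_mean, beta_prior_sd).
//
// All randomness comes from R's RNG (RNGScope), so set.seed() in R makes
// chains exactly reproducible.

#include <Rcpp.h>
using namespace Rcpp;

static inline double bb_core(int k, int n, double p, double u) {
  double a = p * u, b = (1.0 - p) * u;
  return R::lgammafn(k + a) + R::lgammafn(n - k + b) - R::lgammafn(n + u)
       - R::lgammafn(a) - R::lgammafn(b) + R::lgammafn(u);
}

// full beta-binomial log-likelihood of one count table given (p, alpha,
// beta), binomial coefficient included (used by tests as a fixed point
// against independent oracles)
// [[Rcpp::export]]
double bb_loglik_cpp(IntegerMatrix k, IntegerMatrix n, NumericVector p,
                     NumericVector alpha, NumericVector beta) {
  double ll = 0.0;
  for (int i = 0; i < k.nrow(); ++i)
    for (int j = 0; j < k.ncol(); ++j) {
      double u = std::exp(-(alpha[i] + beta[j]));
      ll += R::lchoose(n(i, j), k(i, j)) + bb_core(k(i, j), n(i, j), p[i], u);
    }
  return ll;
}

struct State {
  std::vector<double> p, alpha, beta;
  std::vector<int> incl;
  std::vector<double> ll;      // I x J current log-likelihood terms
  int I, J;
  const IntegerMatrix *k, *n;

  double row_ll(int i, double pi, double ai) const {
    double s = 0.0;
    for (int j = 0; j < J; ++j) {
      double u = std::exp(-(ai + beta[j]));
      s += bb_core((*k)(i, j), (*n)(i, j), pi, u);
    }
    return s;
  }
  double cur_row(int i) const {
    double s = 0.0;
    for (int j = 0; j < J; ++j) s += ll[i * J + j];
    return s;
  }
  void set_row(int i) {
    for (int j = 0; j < J; ++j) {
      double u = std::exp(-(alpha[i] + beta[j]));
      ll[i * J + j] = bb_core((*k)(i, j), (*n)(i, j), p[i], u);
    }
  }
};

// [[Rcpp::export]]
List bayescan_mcmc_cpp(IntegerMatrix kmat, IntegerMatrix nmat,
                       int pilot_runs, int pilot_length,
                       int burnin, int n_iter, int thin,
                       double prior_odds, double alpha_sd_prior,
                       double beta_prior_mean, double beta_prior_sd) {
  RNGScope scope;
  const int I = kmat.nrow(), J = kmat.ncol();
  State st;
  st.I = I; st.J = J; st.k = &kmat; st.n = &nmat;
  st.p.resize(I); st.alpha.assign(I, 0.0); st.incl.assign(I, 0);
  st.beta.assign(J, beta_prior_mean);
  st.ll.assign((size_t)I * J, 0.0);
  for (int i = 0; i < I; ++i) {
    double ks = 1.0, ns = 2.0;
    for (int j = 0; j < J; ++j) { ks += kmat(i, j); ns += nmat(i, j); }
    st.p[i] = ks / ns;
  }
  for (int i = 0; i < I; ++i) st.set_row(i);

  std::vector<double> p_sd(I, 0.6), a_sd(I, 0.6);
  std::vector<double> b_sd(J, 0.3);
  std::vector<int> p_acc(I, 0), p_try(I, 0), a_acc(I, 0), a_try(I, 0);
  std::vector<int> b_acc(J, 0), b_try(J, 0);
  const double log_incl_prior = -std::log(prior_odds); // log P(M1)/P(M0)

  // accumulators (sampling phase)
  std::vector<double> alpha_sum(I, 0.0), alpha_sum_incl(I, 0.0);
  std::vector<int> incl_count(I, 0);
  std::vector<double> beta_sum(J, 0.0);
  int n_rec = n_iter / thin;
  NumericMatrix beta_chain(n_rec, J);
  int rec = 0;

  auto sweep = [&](bool tuning) {
    for (int i = 0; i < I; ++i) {
      // ancestral frequency: random walk on the logit scale
      double lp = std::log(st.p[i] / (1.0 - st.p[i]));
      double lp2 = lp + norm_rand() * p_sd[i];
      double p2 = 1.0 / (1.0 + std::exp(-lp2));
      double cur = st.cur_row(i);
      double prop = st.row_ll(i, p2, st.alpha[i]);
      // uniform prior on p, Jacobian of the logit transform
      double lr = prop - cur +
        std::log(p2 * (1.0 - p2)) - std::log(st.p[i] * (1.0 - st.p[i]));
      p_try[i]++;
      if (std::log(unif_rand()) < lr) {
        st.p[i] = p2; st.set_row(i); cur = prop; p_acc[i]++;
      }
      // alpha random walk (only when included)
      if (st.incl[i]) {
        double a2 = st.alpha[i] + norm_rand() * a_sd[i];
        double prop2 = st.row_ll(i, st.p[i], a2);
        double lr2 = prop2 - cur +
          R::dnorm(a2, 0.0, alpha_sd_prior, 1) -
          R::dnorm(st.alpha[i], 0.0, alpha_sd_prior, 1);
        a_try[i]++;
        if (std::log(unif_rand()) < lr2) {
          st.alpha[i] = a2; st.set_row(i); cur = prop2; a_acc[i]++;
        }
      }
      // reversible jump: toggle inclusion, proposing alpha from the slab
      if (!st.incl[i]) {
        double a2 = norm_rand() * alpha_sd_prior;
        double prop2 = st.row_ll(i, st.p[i], a2);
        // slab prior and proposal cancel; prior odds remain
        double lr2 = prop2 - cur + log_incl_prior;
        if (std::log(unif_rand()) < lr2) {
          st.incl[i] = 1; st.alpha[i] = a2; st.set_row(i);
        }
      } else {
        double prop2 = st.row_ll(i, st.p[i], 0.0);
        double lr2 = prop2 - cur - log_incl_prior;
        if (std::log(unif_rand()) < lr2) {
          st.incl[i] = 0; st.alpha[i] = 0.0; st.set_row(i);
        }
      }
    }
    // population effects
    for (int j = 0; j < J; ++j) {
      double b2 = st.beta[j] + norm_rand() * b_sd[j];
      double cur = 0.0, prop = 0.0;
      std::vector<double> newcol(I);
      for (int i = 0; i < I; ++i) {
        cur += st.ll[i * J + j];
        double u = std::exp(-(st.alpha[i] + b2));
        newcol[i] = bb_core(kmat(i, j), nmat(i, j), st.p[i], u);
        prop += newcol[i];
      }
      double lr = prop - cur +
        R::dnorm(b2, beta_prior_mean, beta_prior_sd, 1) -
        R::dnorm(st.beta[j], beta_prior_mean, beta_prior_sd, 1);
      b_try[j]++;
      if (std::log(unif_rand()) < lr) {
        st.beta[j] = b2; b_acc[j]++;
        for (int i = 0; i < I; ++i) st.ll[i * J + j] = newcol[i];
      }
    }
    (void)tuning;
  };

  auto retune = [](std::vector<double> &sd, std::vector<int> &acc,
                   std::vector<int> &tries) {
    for (size_t t = 0; t < sd.size(); ++t) {
      if (tries[t] == 0) continue;
      double r = (double)acc[t] / tries[t];
      if (r > 0.45) sd[t] *= 1.3;
      else if (r < 0.25) sd[t] /= 1.3;
      acc[t] = 0; tries[t] = 0;
    }
  };

  for (int run = 0; run < pilot_runs; ++run) {
    for (int it = 0; it < pilot_length; ++it) sweep(true);
    retune(p_sd, p_acc, p_try);
    retune(a_sd, a_acc, a_try);
    retune(b_sd, b_acc, b_try);
  }
  for (int it = 0; it < burnin; ++it) sweep(false);
  for (int it = 0; it < n_iter; ++it) {
    sweep(false);
    if ((it + 1) % thin == 0 && rec < n_rec) {
      for (int i = 0; i < I; ++i) {
        alpha_sum[i] += st.alpha[i];
        if (st.incl[i]) { alpha_sum_incl[i] += st.alpha[i]; incl_count[i]++; }
      }
      for (int j = 0; j < J; ++j) {
        beta_sum[j] += st.beta[j];
        beta_chain(rec, j) = st.beta[j];
      }
      rec++;
    }
  }

  NumericVector post_incl(I), alpha_mean(I), alpha_cond(I);
  for (int i = 0; i < I; ++i) {
    post_incl[i] = rec > 0 ? (double)incl_count[i] / rec : NA_REAL;
    alpha_mean[i] = rec > 0 ? alpha_sum[i] / rec : NA_REAL;
    alpha_cond[i] = incl_count[i] > 0 ? alpha_sum_incl[i] / incl_count[i] : 0.0;
  }
  NumericVector beta_mean(J);
  for (int j = 0; j < J; ++j) beta_mean[j] = rec > 0 ? beta_sum[j] / rec : NA_REAL;

  NumericVector p_rate(I), b_rate(J);
  // acceptance counters were reset by pilot tuning; report post-pilot rates
  for (int i = 0; i < I; ++i)
    p_rate[i] = p_try[i] > 0 ? (double)p_acc[i] / p_try[i] : NA_REAL;
  for (int j = 0; j < J; ++j)
    b_rate[j] = b_try[j] > 0 ? (double)b_acc[j] / b_try[j] : NA_REAL;

  return List::create(_["post_incl"] = post_incl,
                      _["alpha_mean"] = alpha_mean,
                      _["alpha_cond"] = alpha_cond,
                      _["beta_mean"] = beta_mean,
                      _["beta_chain"] = beta_chain,
                      _["n_recorded"] = rec,
                      _["p_accept"] = p_rate,
                      _["beta_accept"] = b_rate);
}
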