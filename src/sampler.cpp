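// Metropolis-within-Gibbs sampler for the diet mixing model.
//
// One chain per call. The diet vector p (restricted to the non-excluded
// "active" sources) moves by a logistic-normal random walk on the simplex:
// an additive log-ratio transform of p receives a Gaussian step and the
// Metropolis ratio carries the Jacobian prod(p_i) of the inverse
// transform. Latent source signals and trophic discrimination offsets are
// conjugate given p, so they get exact Gaussian Gibbs updates; an SD of 0
// pins the corresponding latent to its mean. Rank constraints are enforced
// by proposal rejection. All randomness comes from R's RNG, so seeds set
// in R reproduce chains bit-for-bit.

#include <Rcpp.h>
using namespace Rcpp;

namespace {

// expected target value on proxy j: sum_i a_ij (s_ij + d_j), a = p*w normalised
double mix_mean(const NumericVector& p_act, const IntegerVector& active,
                const NumericMatrix& W, const NumericMatrix& s,
                const NumericVector& d, int j, bool& ok) {
  double tot = 0.0, acc = 0.0;
  for (int k = 0; k < active.size(); ++k) {
    int i = active[k];
    double w = p_act[k] * W(i, j);
    tot += w;
    acc += w * (s(i, j) + d[j]);
  }
  if (tot <= 0.0) { ok = false; return 0.0; }
  ok = true;
  return acc / tot;
}

double loglik(const NumericVector& p_act, const IntegerVector& active,
              const NumericMatrix& W, const NumericMatrix& s,
              const NumericVector& d, const NumericVector& Tmean,
              const NumericVector& Tsd) {
  double ll = 0.0;
  for (int j = 0; j < Tmean.size(); ++j) {
    bool ok;
    double mu = mix_mean(p_act, active, W, s, d, j, ok);
    if (!ok) return R_NegInf;
    ll += R::dnorm(Tmean[j], mu, Tsd[j], 1);
  }
  return ll;
}

// Dirichlet(alpha) log-kernel plus the log-Jacobian of the alr transform
double logprior_jac(const NumericVector& p_act, const NumericVector& alpha) {
  double lp = 0.0;
  for (int k = 0; k < p_act.size(); ++k) {
    if (p_act[k] <= 0.0) return R_NegInf;
    lp += (alpha[k] - 1.0) * std::log(p_act[k]) + std::log(p_act[k]);
  }
  return lp;
}

// strict-decrease check along each constraint chain (full-index space)
bool admissible(const NumericVector& p_full, const List& constraints) {
  for (int c = 0; c < constraints.size(); ++c) {
    IntegerVector chain = constraints[c];
    for (int k = 1; k < chain.size(); ++k)
      if (p_full[chain[k]] >= p_full[chain[k - 1]]) return false;
  }
  return true;
}

}  // namespace

// [[Rcpp::export(name = ".dm_run_chain")]]
List dm_run_chain(NumericMatrix S, NumericMatrix Ssd, NumericMatrix W,
                  NumericVector Tmean, NumericVector Tsd,
                  NumericVector offset_mean, NumericVector offset_sd,
                  NumericVector alpha, List constraints, IntegerVector active,
                  NumericVector p_init_act, bool use_likelihood,
                  int n_iterations, int n_burnin, int thin, double step_scale) {
  const int K = S.nrow(), J = S.ncol(), A = active.size();
  NumericVector p_act = clone(p_init_act);
  NumericMatrix s = clone(S);
  NumericVector d = clone(offset_mean);
  NumericVector p_full(K);
  for (int k = 0; k < A; ++k) p_full[active[k]] = p_act[k];

  const int n_keep = (n_iterations - n_burnin) / thin;
  NumericMatrix out_p(n_keep, K);
  NumericMatrix out_d(n_keep, J);
  int kept = 0;
  long accepted = 0;

  NumericVector z(A - 1), z_prop(A - 1), p_prop(A), p_full_prop(K);
  for (int k = 0; k < A - 1; ++k) z[k] = std::log(p_act[k] / p_act[A - 1]);

  double ll_cur = use_likelihood
      ? loglik(p_act, active, W, s, d, Tmean, Tsd) : 0.0;
  double lp_cur = logprior_jac(p_act, alpha);

  for (int it = 1; it <= n_iterations; ++it) {
    // --- Metropolis update of p on the simplex ---
    for (int k = 0; k < A - 1; ++k) z_prop[k] = z[k] + step_scale * norm_rand();
    double zmax = 0.0;
    for (int k = 0; k < A - 1; ++k) if (z_prop[k] > zmax) zmax = z_prop[k];
    double denom = std::exp(-zmax);
    for (int k = 0; k < A - 1; ++k) denom += std::exp(z_prop[k] - zmax);
    for (int k = 0; k < A - 1; ++k) p_prop[k] = std::exp(z_prop[k] - zmax) / denom;
    p_prop[A - 1] = std::exp(-zmax) / denom;

    std::fill(p_full_prop.begin(), p_full_prop.end(), 0.0);
    for (int k = 0; k < A; ++k) p_full_prop[active[k]] = p_prop[k];

    if (admissible(p_full_prop, constraints)) {
      double lp_prop = logprior_jac(p_prop, alpha);
      double ll_prop = use_likelihood
          ? loglik(p_prop, active, W, s, d, Tmean, Tsd) : 0.0;
      double lr = (ll_prop + lp_prop) - (ll_cur + lp_cur);
      if (std::isfinite(lr) && std::log(unif_rand()) < lr) {
        z = clone(z_prop);
        p_act = clone(p_prop);
        p_full = clone(p_full_prop);
        ll_cur = ll_prop;
        lp_cur = lp_prop;
        ++accepted;
      }
    }

    // --- Gibbs updates of latent source signals (active sources only) ---
    for (int j = 0; j < J; ++j) {
      double tot = 0.0;
      for (int k = 0; k < A; ++k) tot += p_act[k] * W(active[k], j);
      for (int k = 0; k < A; ++k) {
        int i = active[k];
        if (Ssd(i, j) <= 0.0) continue;
        double prior_prec = 1.0 / (Ssd(i, j) * Ssd(i, j));
        if (!use_likelihood) {
          s(i, j) = R::rnorm(S(i, j), Ssd(i, j));
          continue;
        }
        double a = p_act[k] * W(i, j) / tot;
        double rest = 0.0;
        for (int k2 = 0; k2 < A; ++k2)
          if (k2 != k) rest += p_act[k2] * W(active[k2], j) / tot * s(active[k2], j);
        double lik_prec = a * a / (Tsd[j] * Tsd[j]);
        double prec = prior_prec + lik_prec;
        double mean = (S(i, j) * prior_prec +
                       a * (Tmean[j] - rest - d[j]) / (Tsd[j] * Tsd[j])) / prec;
        s(i, j) = R::rnorm(mean, 1.0 / std::sqrt(prec));
      }
    }

    // --- Gibbs updates of realized discrimination offsets ---
    for (int j = 0; j < J; ++j) {
      if (offset_sd[j] <= 0.0) continue;
      double prior_prec = 1.0 / (offset_sd[j] * offset_sd[j]);
      if (!use_likelihood) {
        d[j] = R::rnorm(offset_mean[j], offset_sd[j]);
        continue;
      }
      double tot = 0.0, m = 0.0;
      for (int k = 0; k < A; ++k) tot += p_act[k] * W(active[k], j);
      for (int k = 0; k < A; ++k)
        m += p_act[k] * W(active[k], j) / tot * s(active[k], j);
      double prec = prior_prec + 1.0 / (Tsd[j] * Tsd[j]);
      double mean = (offset_mean[j] * prior_prec +
                     (Tmean[j] - m) / (Tsd[j] * Tsd[j])) / prec;
      d[j] = R::rnorm(mean, 1.0 / std::sqrt(prec));
    }

    if (use_likelihood)  // s and d moved; refresh the cached likelihood
      ll_cur = loglik(p_act, active, W, s, d, Tmean, Tsd);

    if (it > n_burnin && (it - n_burnin) % thin == 0 && kept < n_keep) {
      for (int i = 0; i < K; ++i) out_p(kept, i) = p_full[i];
      for (int j = 0; j < J; ++j) out_d(kept, j) = d[j];
      ++kept;
    }
  }

  return List::create(_["p"] = out_p, _["offsets"] = out_d,
                      _["acceptance_rate"] = double(accepted) / n_iterations);
}
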