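// Core numerics for the bounded CFA parameterization: marginal
// log-likelihood from the sample covariance matrix, and the adaptive
// Metropolis-within-Gibbs sweep. Kept in C++ because the sampler evaluates
// the likelihood q times per iteration.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Model-implied covariance under the bounded parameterization.
// lam: one standardized loading per item; group: factor index (1-based) per
// item; rho: correlation between the two factors; sig: per-item SDs.
static arma::mat implied_sigma(const arma::vec& lam, double rho,
                               const arma::vec& sig,
                               const arma::ivec& group) {
  const int p = lam.n_elem;
  arma::mat out(p, p);
  for (int i = 0; i < p; ++i) {
    for (int j = 0; j <= i; ++j) {
      double v;
      if (i == j) {
        v = sig[i] * sig[i];
      } else {
        double phi = (group[i] == group[j]) ? 1.0 : rho;
        v = sig[i] * sig[j] * lam[i] * lam[j] * phi;
      }
      out(i, j) = v;
      out(j, i) = v;
    }
  }
  return out;
}

// -(n/2) [p log 2pi + log|Sigma| + tr(Sigma^{-1} S)]; -Inf when Sigma is
// not positive definite (so optimizers/samplers reject such points).
static double loglik_from_sigma(const arma::mat& sigma, const arma::mat& S,
                                double n) {
  arma::mat R;
  if (!arma::chol(R, sigma)) return R_NegInf;
  const int p = sigma.n_rows;
  double logdet = 2.0 * arma::accu(arma::log(R.diag()));
  arma::mat Y = arma::solve(arma::trimatl(R.t()), S);
  arma::mat Z = arma::solve(arma::trimatu(R), Y);
  double tr = arma::trace(Z);
  return -0.5 * n * (p * std::log(2.0 * M_PI) + logdet + tr);
}

// [[Rcpp::export]]
double cpp_loglik(const arma::vec& lam, double rho, const arma::vec& sig,
                  const arma::ivec& group, const arma::mat& S, double n) {
  return loglik_from_sigma(implied_sigma(lam, rho, sig, group), S, n);
}

// [[Rcpp::export]]
double cpp_loglik_sigma(const arma::mat& sigma, const arma::mat& S, double n) {
  return loglik_from_sigma(sigma, S, n);
}

// Beta4(a, b, l, u) log-density (total function).
static double beta4_logpdf(double x, double a, double b, double l, double u) {
  if (x <= l || x >= u) return R_NegInf;
  double z = (x - l) / (u - l);
  return (a - 1.0) * std::log(z) + (b - 1.0) * std::log1p(-z) -
         R::lbeta(a, b) - std::log(u - l);
}

// Batch adaptation of a proposal SD toward the target acceptance rate.
static double adapt_tau(double tau, double rstar, double r, double delta) {
  if (rstar > r + delta) {
    return tau * (2.0 - (1.0 - rstar) / (1.0 - r));
  } else if (rstar < r - delta) {
    return tau / (2.0 - rstar / r);
  }
  return tau;
}

struct ParamPrior {
  int type; // 0 = beta4, 1 = improper flat on (0, Inf)
  double a, b, l, u;
};

static double log_prior_d(double x, const ParamPrior& pr) {
  if (pr.type == 1) return (x > 0.0) ? 0.0 : R_NegInf;
  return beta4_logpdf(x, pr.a, pr.b, pr.l, pr.u);
}

// Adaptive Metropolis-within-Gibbs on the marginal likelihood.
//
// Parameter vector layout: [lambda params (n_lam), rho, sigma params (p if
// sigma_free)]. lambda_idx maps each item to its loading parameter (0-based),
// which covers both the free-loading model (n_lam = p) and the equal-loading
// model (n_lam = 1). Proposal SDs are adapted in batches during burn-in only.
// Uses R's RNG so results are reproducible via set.seed().
// [[Rcpp::export]]
List cpp_run_chain(const arma::mat& S, double n, const arma::ivec& group,
                   const arma::ivec& lambda_idx, bool sigma_free,
                   const arma::vec& sigma_fixed, const arma::vec& start,
                   int iters, int burnin, int batch,
                   double target_acc, double tol,
                   const arma::vec& tau_init,
                   double lam_a, double lam_b, double lam_l, double lam_u,
                   double rho_a, double rho_b, double rho_l, double rho_u) {
  const int p = group.n_elem;
  int n_lam = lambda_idx.max() + 1;
  const int q = n_lam + 1 + (sigma_free ? p : 0);
  if ((int)start.n_elem != q || (int)tau_init.n_elem != q)
    stop("start/tau length does not match the number of parameters");

  std::vector<ParamPrior> priors(q);
  for (int d = 0; d < n_lam; ++d)
    priors[d] = ParamPrior{0, lam_a, lam_b, lam_l, lam_u};
  priors[n_lam] = ParamPrior{0, rho_a, rho_b, rho_l, rho_u};
  for (int d = n_lam + 1; d < q; ++d)
    priors[d] = ParamPrior{1, 0, 0, 0, 0};

  arma::vec theta = start;
  arma::vec tau = tau_init;

  // scratch copies of the item-level parameters
  arma::vec lam_items(p), sig_items(p);
  auto refresh_items = [&](const arma::vec& th) {
    for (int j = 0; j < p; ++j) {
      lam_items[j] = th[lambda_idx[j]];
      sig_items[j] = sigma_free ? th[n_lam + 1 + j] : sigma_fixed[j];
    }
  };
  refresh_items(theta);
  double ll_curr = loglik_from_sigma(
      implied_sigma(lam_items, theta[n_lam], sig_items, group), S, n);
  if (!std::isfinite(ll_curr))
    stop("starting values give a non-positive-definite implied covariance");

  const int keep = iters - burnin;
  arma::mat draws(keep, q);
  arma::vec logpost(keep);
  arma::ivec acc_batch(q, arma::fill::zeros);
  arma::ivec acc_post(q, arma::fill::zeros);

  for (int t = 0; t < iters; ++t) {
    for (int d = 0; d < q; ++d) {
      double curr = theta[d];
      double prop = curr + tau[d] * norm_rand();
      double lpr_prop = log_prior_d(prop, priors[d]);
      bool accept = false;
      if (std::isfinite(lpr_prop)) {
        theta[d] = prop;
        refresh_items(theta);
        double ll_prop = loglik_from_sigma(
            implied_sigma(lam_items, theta[n_lam], sig_items, group), S, n);
        double lpr_curr = log_prior_d(curr, priors[d]);
        double logM = (ll_prop + lpr_prop) - (ll_curr + lpr_curr);
        if (std::isfinite(ll_prop) && std::log(unif_rand()) < logM) {
          accept = true;
          ll_curr = ll_prop;
        } else {
          theta[d] = curr;
          refresh_items(theta);
        }
      }
      if (accept) {
        acc_batch[d] += 1;
        if (t >= burnin) acc_post[d] += 1;
      }
    }
    if (t < burnin && (t + 1) % batch == 0) {
      for (int d = 0; d < q; ++d) {
        double rstar = (double)acc_batch[d] / batch;
        tau[d] = adapt_tau(tau[d], rstar, target_acc, tol);
      }
      acc_batch.zeros();
    }
    if (t >= burnin) {
      int k = t - burnin;
      draws.row(k) = theta.t();
      double lp = ll_curr;
      for (int d = 0; d <= n_lam; ++d) lp += log_prior_d(theta[d], priors[d]);
      logpost[k] = lp;
    }
  }

  arma::vec acc_rate(q);
  for (int d = 0; d < q; ++d) acc_rate[d] = (double)acc_post[d] / keep;

  return List::create(_["draws"] = draws,
                      _["logpost"] = logpost,
                      _["acceptance"] = acc_rate,
                      _["tau_final"] = tau,
                      _["n_lambda_params"] = n_lam);
}
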