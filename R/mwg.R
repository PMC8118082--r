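# Adaptive Metropolis-within-Gibbs sampling on the marginal CFA likelihood.
#
# Canonical parameter ordering used by the sampler and all chain summaries:
# lambda parameters first (one per indicator, or a single shared loading for
# an equal-loading spec), then the latent correlation rho, then the indicator
# SDs sigma_1..sigma_p (absent when the spec fixes them).

# Canonical parameter names for a spec.
param_names <- function(spec) {
  n_lam <- if (spec$equal_loadings) 1L else spec$p
  nm <- c(if (n_lam == 1L) "lambda" else paste0("lambda", seq_len(n_lam)), "rho")
  if (is.null(spec$fixed_sigma)) nm <- c(nm, paste0("sigma", seq_len(spec$p)))
  nm
}

# Map a canonical parameter vector to a cfa_parameters object.
theta_from_vec <- function(v, spec) {
  n_lam <- if (spec$equal_loadings) 1L else spec$p
  lam <- v[seq_len(n_lam)]
  if (n_lam == 1L) lam <- rep(lam, spec$p)
  rho <- v[n_lam + 1L]
  sds <- if (is.null(spec$fixed_sigma)) v[n_lam + 1L + seq_len(spec$p)] else spec$fixed_sigma
  cfa_parameters(lam, rho, sds, spec = spec)
}

vec_from_theta <- function(theta, spec) {
  lam <- if (spec$equal_loadings) theta$loadings[1] else theta$loadings
  v <- c(lam, theta$rho)
  if (is.null(spec$fixed_sigma)) v <- c(v, theta$sds)
  stats::setNames(v, param_names(spec))
}

#' Configuration for the adaptive Metropolis-within-Gibbs sampler
#'
#' Defaults follow the simulation settings used throughout the package: 5000
#' iterations with the first 2500 discarded as burn-in, proposal standard
#' deviations adapted in batches of 50 iterations during burn-in only, with a
#' target acceptance rate of 0.45 and tolerance 0.10.
#'
#' @param iters Total iterations `T`.
#' @param burnin Burn-in iterations (< `iters`); proposal adaptation stops
#'   here and only post-burn-in draws are retained.
#' @param batch Batch size for acceptance-rate monitoring during burn-in.
#' @param target_acceptance Target acceptance rate `r`.
#' @param tolerance Half-width `delta` of the no-adaptation band
#'   `(r - delta, r + delta)`.
#' @param tau Optional named or positional vector of initial proposal SDs (one
#'   per parameter). Default: 0.2 for loadings and the correlation, and
#'   `0.5 * sqrt(diag(S))` for the indicator SDs.
#' @param seed Optional integer seed for reproducible chains.
#' @return Object of class `"chain_config"`.
#' @export
chain_config <- function(iters = 5000, burnin = 2500, batch = 50,
                         target_acceptance = 0.45, tolerance = 0.10,
                         tau = NULL, seed = NULL) {
  stopifnot(burnin < iters, burnin >= 0, batch >= 1)
  r <- target_acceptance; d <- tolerance
  if (!(r - d > 0 && r + d < 1)) stop("need 0 < r - delta < r + delta < 1")
  structure(list(iters = as.integer(iters), burnin = as.integer(burnin),
                 batch = as.integer(batch), target_acceptance = r,
                 tolerance = d, tau = tau, seed = seed),
            class = "chain_config")
}

#' Batch adaptation rule for a proposal standard deviation
#'
#' If the empirical acceptance rate `r_star` of the last batch exceeds
#' \eqn{r + \delta}, the proposal SD is inflated by `2 - (1 - r_star)/(1 - r)`;
#' if it falls below \eqn{r - \delta}, the SD is divided by `2 - r_star/r`;
#' otherwise
#' it is left unchanged.
#'
#' @param tau_prev Proposal SD used in the last batch.
#' @param r_star Empirical acceptance rate of the last batch.
#' @param r Target acceptance rate.
#' @param delta Tolerance half-width.
#' @return Updated proposal SD (vectorized over its arguments).
#' @examples
#' adapt_proposal_sd(1, 0.90, 0.45, 0.10) # inflated by 1.8182
#' adapt_proposal_sd(1, 0.45, 0.45, 0.10) # unchanged
#' @export
adapt_proposal_sd <- function(tau_prev, r_star, r = 0.45, delta = 0.10) {
  up <- r_star > r + delta
  down <- r_star < r - delta
  out <- tau_prev
  out[up] <- tau_prev[up] * (2 - (1 - r_star[up]) / (1 - r))
  out[down] <- tau_prev[down] / (2 - r_star[down] / r)
  out
}

#' Log Metropolis-Hastings ratio for one parameter component
#'
#' The sampler updates one coordinate at a time with a symmetric normal
#' proposal, so the log ratio is the difference of (log-likelihood + log-prior
#' of the updated component) at the proposed versus current value, holding all
#' other components at their latest values. Proposals outside the prior
#' support return `-Inf` (automatic rejection).
#'
#' @param prop Proposed value of component `d`.
#' @param curr Current value of component `d`.
#' @param d Index of the component in the canonical parameter ordering
#'   (loadings, correlation, indicator SDs).
#' @param theta_vec Current canonical parameter vector.
#' @param moments A [sample_moments()] object.
#' @param spec A [cfa_model_spec()].
#' @param priors A [prior_config()].
#' @return Scalar log MH ratio.
#' @export
mh_log_ratio <- function(prop, curr, d, theta_vec, moments,
                         spec = cfa_model_spec(), priors = uniform_priors(spec)) {
  n_lam <- if (spec$equal_loadings) 1L else spec$p
  lp1 <- component_log_prior(prop, d, n_lam, priors)
  if (!is.finite(lp1)) return(-Inf)
  lp0 <- component_log_prior(curr, d, n_lam, priors)
  v1 <- v0 <- theta_vec
  v1[d] <- prop
  v0[d] <- curr
  ll1 <- tryCatch(log_likelihood(theta_from_vec(v1, spec), moments, spec),
                  error = function(e) -Inf)
  ll0 <- log_likelihood(theta_from_vec(v0, spec), moments, spec)
  (ll1 + lp1) - (ll0 + lp0)
}

component_log_prior <- function(x, d, n_lam, priors) {
  if (d <= n_lam) {
    beta4_logpdf(x, priors$lambda)
  } else if (d == n_lam + 1L) {
    beta4_logpdf(x, priors$rho)
  } else {
    if (x > 0) 0 else -Inf
  }
}

#' Run the adaptive Metropolis-within-Gibbs sampler
#'
#' Sweeps the parameters in a fixed order each iteration, updating each with a
#' symmetric normal proposal on the marginal likelihood (Metropolis step
#' within a Gibbs cycle). Proposal SDs are adapted toward the target
#' acceptance rate in batches during burn-in and frozen afterwards. Proposals
#' outside the prior support (including non-positive SDs) are rejected and the
#' current value retained, so every retained draw lies in the admissible box.
#'
#' @param moments A [sample_moments()] object.
#' @param spec A [cfa_model_spec()].
#' @param priors A [prior_config()].
#' @param config A [chain_config()].
#' @param start Optional canonical start vector; default: loadings 0.5,
#'   correlation 0, SDs `sqrt(diag(S))`.
#' @return Object of class `"posterior_chain"`: `draws` (retained iterations x
#'   parameters, named columns), `logpost` (unnormalized log posterior per
#'   retained draw), `acceptance` (post-burn-in acceptance rate per
#'   parameter), `tau_final`, `spec`, `priors`, `config`.
#' @examples
#' spec <- cfa_model_spec()
#' th <- cfa_parameters(0.5, 0.7, spec = spec)
#' mom <- sample_moments(implied_covariance(th, spec), n = 30)
#' ch <- run_chain(mom, spec, config = chain_config(iters = 500, burnin = 250,
#'                                                  seed = 1))
#' colMeans(ch$draws)
#' @export
run_chain <- function(moments, spec = cfa_model_spec(),
                      priors = uniform_priors(spec),
                      config = chain_config(), start = NULL) {
  p <- spec$p
  n_lam <- if (spec$equal_loadings) 1L else p
  sigma_free <- is.null(spec$fixed_sigma)
  q <- n_lam + 1L + if (sigma_free) p else 0L
  nm <- param_names(spec)
  if (is.null(start)) {
    start <- c(rep(0.5, n_lam), 0,
               if (sigma_free) sqrt(diag(moments$cov)))
  }
  if (length(start) != q) stop("start must have length ", q)
  tau <- config$tau
  if (is.null(tau)) {
    tau <- c(rep(0.2, n_lam + 1L),
             if (sigma_free) 0.5 * sqrt(diag(moments$cov)))
  }
  if (length(tau) != q) stop("tau must have length ", q)
  if (!is.null(config$seed)) set.seed(config$seed)
  lam_idx <- if (spec$equal_loadings) rep(0L, p) else seq_len(p) - 1L
  res <- cpp_run_chain(
    moments$cov, moments$n, as.integer(spec$loading_map), lam_idx,
    sigma_free, if (sigma_free) rep(1, p) else spec$fixed_sigma,
    start, config$iters, config$burnin, config$batch,
    config$target_acceptance, config$tolerance, tau,
    priors$lambda$a, priors$lambda$b, priors$lambda$l, priors$lambda$u,
    priors$rho$a, priors$rho$b, priors$rho$l, priors$rho$u
  )
  draws <- res$draws
  colnames(draws) <- nm
  structure(list(draws = draws, logpost = as.numeric(res$logpost),
                 acceptance = stats::setNames(as.numeric(res$acceptance), nm),
                 tau_final = stats::setNames(as.numeric(res$tau_final), nm),
                 spec = spec, priors = priors, config = config),
            class = "posterior_chain")
}

#' @export
print.posterior_chain <- function(x, ...) {
  cat("Posterior chain:", nrow(x$draws), "retained draws,",
      ncol(x$draws), "parameters\n")
  cat("  acceptance rates:",
      paste(sprintf("%s=%.2f", colnames(x$draws), x$acceptance), collapse = " "),
      "\n")
  invisible(x)
}

#' Point estimates and credible intervals from a posterior chain
#'
#' Computes, per parameter: the posterior mean (EAP), the sample median (Med),
#' the mode of a Gaussian kernel density estimate (MAP; Silverman bandwidth,
#' mode located on a 512-point grid over the draw range), and the central 95%
#' credibility interval (2.5th and 97.5th percentiles). The multivariate-mode
#' proxy `pml_mcmc` is the retained draw with the highest unnormalized log
#' posterior.
#'
#' @param chain A [run_chain()] result.
#' @return List with named vectors `eap`, `med`, `map`, matrix `bci`
#'   (rows `lower`/`upper`), and `pml_mcmc`.
#' @export
chain_point_estimates <- function(chain) {
  draws <- chain$draws
  eap <- colMeans(draws)
  med <- apply(draws, 2, stats::median)
  map <- apply(draws, 2, kde_mode)
  bci <- apply(draws, 2, stats::quantile, probs = c(0.025, 0.975), names = FALSE)
  rownames(bci) <- c("lower", "upper")
  pml <- draws[which.max(chain$logpost), ]
  list(eap = eap, med = med, map = map, bci = bci, pml_mcmc = pml)
}

# Mode of a univariate Gaussian KDE; degenerate samples return their value.
kde_mode <- function(x) {
  if (stats::sd(x) < .Machine$double.eps^0.5) return(x[1])
  d <- stats::density(x, bw = "nrd0", n = 512)
  d$x[which.max(d$y)]
}

#' Convergence diagnostics: potential scale reduction and effective sample size
#'
#' The potential scale reduction factor (PSR) compares between-chain and
#' within-chain variances; values near 1 indicate mixing. With a single chain
#' the split-chain variant is used (first half vs second half). The effective
#' sample size (ESS) divides the total number of draws by
#' `1 + 2 * sum(rho_k)`, truncating the autocorrelation sum at the first
#' non-positive lag.
#'
#' @param chains A [run_chain()] result, a list of them, or a numeric matrix
#'   (draws x parameters) / list of matrices.
#' @return List with named vectors `psr` and `ess`, or `NULL` (with a warning)
#'   when the chains are too short (< 10 draws per split).
#' @export
mcmc_diagnostics <- function(chains) {
  mats <- chains_as_matrices(chains)
  if (length(mats) == 1L) {
    m <- mats[[1]]
    half <- floor(nrow(m) / 2)
    mats <- list(m[seq_len(half), , drop = FALSE],
                 m[nrow(m) - half + seq_len(half), , drop = FALSE])
  }
  len <- min(vapply(mats, nrow, 0L))
  if (len < 10) {
    warning("chains too short for diagnostics")
    return(NULL)
  }
  mats <- lapply(mats, function(m) m[seq_len(len), , drop = FALSE])
  q <- ncol(mats[[1]])
  nm <- colnames(mats[[1]])
  psr <- vapply(seq_len(q), function(j) {
    per <- lapply(mats, function(m) m[, j])
    psr_one(per)
  }, 0)
  ess <- vapply(seq_len(q), function(j) {
    sum(vapply(mats, function(m) ess_one(m[, j]), 0))
  }, 0)
  list(psr = stats::setNames(psr, nm), ess = stats::setNames(ess, nm))
}

chains_as_matrices <- function(chains) {
  if (inherits(chains, "posterior_chain")) return(list(chains$draws))
  if (is.matrix(chains)) return(list(chains))
  if (is.numeric(chains)) return(list(matrix(chains, ncol = 1)))
  lapply(chains, function(ch) {
    if (inherits(ch, "posterior_chain")) ch$draws
    else if (is.matrix(ch)) ch
    else matrix(ch, ncol = 1)
  })
}

psr_one <- function(per_chain) {
  m <- length(per_chain)
  n <- length(per_chain[[1]])
  means <- vapply(per_chain, mean, 0)
  vars <- vapply(per_chain, stats::var, 0)
  W <- mean(vars)
  B_over_n <- stats::var(means)
  if (W <= 0) {
    if (B_over_n > 0) return(Inf)
    return(1)
  }
  var_plus <- (n - 1) / n * W + B_over_n
  sqrt(var_plus / W)
}

ess_one <- function(x) {
  n <- length(x)
  if (stats::sd(x) == 0) return(0)
  r <- stats::acf(x, lag.max = min(n - 1, 10 * ceiling(log10(n)) * 10),
                  plot = FALSE)$acf[-1]
  pos <- which(r <= 0)
  if (length(pos)) r <- r[seq_len(pos[1] - 1)]
  n / (1 + 2 * sum(r))
}
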