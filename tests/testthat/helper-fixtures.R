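# Shared fixtures: specs, idealized moments, random admissible parameters.

two_factor_spec <- function() cfa_model_spec(c(1, 1, 1, 2, 2, 2))

equal_spec <- function() {
  cfa_model_spec(equal_loadings = TRUE, fixed_sigma = rep(1, 6))
}

# Moments with S set exactly to the model-implied covariance.
idealized_moments <- function(rho = 0.7, lambda = 0.5, n = 30,
                              spec = two_factor_spec()) {
  th <- cfa_parameters(lambda, rho, spec = spec)
  sample_moments(implied_covariance(th, spec), n = n)
}

# Random admissible parameter draw for a spec.
random_theta <- function(spec) {
  cfa_parameters(stats::runif(spec$p, 0.1, 0.9), stats::runif(1, -0.9, 0.9),
                 stats::runif(spec$p, 0.5, 2), spec = spec)
}

# Explicit-matrix oracle for the implied covariance: scale matrix times
# standardized loading structure, assembled element by element.
oracle_implied_cov <- function(theta, spec) {
  p <- spec$p
  L <- matrix(0, p, spec$m)
  L[cbind(seq_len(p), spec$loading_map)] <- theta$loadings
  D <- diag(theta$sds, p)
  Omega <- diag(1 - theta$loadings^2, p)
  D %*% (L %*% theta$phi %*% t(L) + Omega) %*% D
}
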