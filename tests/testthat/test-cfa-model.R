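test_that("implied covariance reproduces the block structure", {
  spec <- two_factor_spec()
  th <- cfa_parameters(0.5, 0.7, spec = spec)
  sig <- implied_covariance(th, spec)
  expect_equal(diag(sig), rep(1, 6))
  expect_equal(sig[1, 2], 0.25) # within-factor
  expect_equal(sig[1, 4], 0.175) # cross-factor: 0.25 * 0.7
  expect_equal(sig, t(sig))

  # near-zero loadings: covariance collapses to diag(sigma_j^2)
  th0 <- cfa_parameters(rep(1e-9, 6), 0.5, sds = c(1, 2, 3, 1, 2, 3),
                        spec = spec)
  expect_equal(implied_covariance(th0, spec), diag(c(1, 4, 9, 1, 4, 9)),
               tolerance = 1e-8)

  # hand-checked cross-factor entry with unequal loadings and scales
  lam <- c(0.3, 0.4, 0.5, 0.6, 0.7, 0.8)
  sds <- c(2, 1.5, 1, 1, 2.5, 3)
  th2 <- cfa_parameters(lam, 0.5, sds, spec = spec)
  sig2 <- implied_covariance(th2, spec)
  expect_equal(sig2[1, 4], 2 * 1 * 0.3 * 0.6 * 0.5)
  expect_equal(sig2[2, 3], 1.5 * 1 * 0.4 * 0.5)
})

test_that("implied covariance equals the explicit-matrix oracle on random draws", {
  spec <- two_factor_spec()
  set.seed(101)
  for (i in 1:1000) {
    th <- random_theta(spec)
    expect_equal(implied_covariance(th, spec), oracle_implied_cov(th, spec),
                 tolerance = 1e-12)
  }
})

test_that("implied covariance is positive definite over the admissible box", {
  spec <- two_factor_spec()
  for (lam in c(0.01, 0.3, 0.6, 0.95, 0.999)) {
    for (rho in c(-0.999, -0.5, 0, 0.5, 0.999)) {
      th <- cfa_parameters(lam, rho, spec = spec)
      expect_no_error(chol(implied_covariance(th, spec)))
    }
  }
})

test_that("log-likelihood matches the closed form at saturated moments", {
  spec <- two_factor_spec()
  th <- cfa_parameters(0.5, 0.7, spec = spec)
  S <- implied_covariance(th, spec)
  mom <- sample_moments(S, n = 30)
  expect_equal(log_likelihood(th, mom, spec),
               -(30 / 2) * (6 * log(2 * pi) + determinant(S)$modulus[1] + 6))

  # identity covariance: l = -(n/2) p (log 2pi + 1)
  th0 <- cfa_parameters(rep(1e-9, 6), 1e-9, spec = spec)
  mom_id <- sample_moments(diag(6), n = 30)
  expect_equal(log_likelihood(th0, mom_id, spec), -90 * (log(2 * pi) + 1),
               tolerance = 1e-6)

  # linear in n
  mom2 <- sample_moments(S, n = 60)
  expect_equal(log_likelihood(th, mom2, spec),
               2 * log_likelihood(th, mom, spec))
})

test_that("saturated moments maximize the likelihood locally", {
  spec <- two_factor_spec()
  th <- cfa_parameters(0.5, 0.7, spec = spec)
  mom <- idealized_moments(0.7, 0.5, 30)
  l0 <- log_likelihood(th, mom, spec)
  set.seed(7)
  for (i in 1:50) {
    d <- 0.02 * stats::rnorm(13)
    thp <- cfa_parameters(th$loadings + d[1:6], th$rho + d[7],
                          th$sds * exp(0.02 * d[8:13]), spec = spec)
    expect_lt(log_likelihood(thp, mom, spec), l0)
  }
})

test_that("cpp and R likelihoods agree", {
  spec <- two_factor_spec()
  set.seed(5)
  x <- gen_normal(cfa_parameters(0.5, 0.3, spec = spec), spec, 40)
  mom <- moments_from_data(x)
  for (i in 1:50) {
    th <- random_theta(spec)
    expect_equal(
      log_likelihood(th, mom, spec),
      smallcfa:::cpp_loglik(th$loadings, th$rho, th$sds,
                            spec$loading_map, mom$cov, mom$n),
      tolerance = 1e-10
    )
  }
})

test_that("non-positive-definite implied covariance follows the -Inf contract", {
  spec <- two_factor_spec()
  th <- cfa_parameters(0.5, 0.7, spec = spec)
  mom <- sample_moments(diag(6), n = 30)
  bad <- diag(6)
  bad[1, 1] <- -1
  expect_equal(smallcfa:::loglik_sigma(bad, mom$cov, 30), -Inf)
  expect_error(smallcfa:::loglik_sigma(bad, mom$cov, 30, on_nonpd = "error"),
               "positive definite")
})

test_that("reliability algebra reproduces the loading/reliability table", {
  tab <- rbind(
    c(0.35, 0.13, 0.30), c(0.43, 0.18, 0.40), c(0.50, 0.25, 0.50),
    c(0.58, 0.33, 0.60), c(0.66, 0.44, 0.70), c(0.76, 0.57, 0.80),
    c(0.87, 0.75, 0.90)
  )
  for (i in seq_len(nrow(tab))) {
    # the table derives from exact sum-score reliabilities: invert, then round
    lam_exact <- loading_from_reliability(tab[i, 3], 3)
    expect_equal(round(lam_exact, 2), tab[i, 1])
    expect_equal(round(lam_exact^2, 2), tab[i, 2])
    expect_equal(round(reliability_sum(tab[i, 1], 3), 2), tab[i, 3])
  }
  expect_equal(reliability_sum(0.5, 1), 0.25) # I = 1 reduces to lambda^2
  expect_equal(loading_from_reliability(0.5, 1), sqrt(0.5))
})

test_that("reliability maps are mutually inverse and monotone", {
  set.seed(2)
  for (i in 1:50) {
    rel <- stats::runif(1, 0.05, 0.95)
    I <- sample(1:10, 1)
    lam <- loading_from_reliability(rel, I)
    expect_equal(reliability_sum(lam, I), rel, tolerance = 1e-10)
  }
  expect_true(all(diff(reliability_sum(seq(0.1, 0.9, 0.1), 3)) > 0))
  expect_true(all(diff(sapply(1:10, function(I) reliability_sum(0.5, I))) > 0))
  expect_error(reliability_sum(1.2, 3), "strictly in")
  expect_error(loading_from_reliability(1.2, 3), "strictly in")
})

test_that("standardization round-trips with the unstandardized scale", {
  expect_equal(standardize_parameters(0.5, 0.75),
               list(sigma = 1, lambda_std = 0.5, resid_std = 0.75))
  expect_equal(standardize_parameters(1, 3),
               list(sigma = 2, lambda_std = 0.5, resid_std = 0.75))
  z <- standardize_parameters(0, 4)
  expect_equal(z$lambda_std, 0)
  expect_equal(z$sigma, 2)
  set.seed(3)
  for (i in 1:50) {
    lam_u <- stats::rnorm(1)
    om <- stats::runif(1, 0.1, 4)
    s <- standardize_parameters(lam_u, om)
    back <- unstandardize_parameters(s$lambda_std, s$sigma)
    expect_equal(back$lambda_unstd, lam_u, tolerance = 1e-12)
    expect_equal(back$resid_var, om, tolerance = 1e-12)
  }
  expect_error(standardize_parameters(1, -1), "positive")
})

test_that("model spec and parameter validation reject bad input", {
  expect_error(cfa_model_spec(c(1, 1, 2)), "two indicators per factor")
  expect_error(cfa_model_spec(c(1, 1, 3, 3)), "consecutive")
  expect_error(cfa_model_spec(epsilon = 0), "epsilon")
  spec <- two_factor_spec()
  expect_error(cfa_parameters(1.2, 0.5, spec = spec), "strictly in")
  expect_error(cfa_parameters(0.5, 1.5, spec = spec), "rho")
  expect_error(cfa_parameters(0.5, 0.5, sds = -1, spec = spec), "positive")
  expect_warning(sample_moments(matrix(c(1, 2, 2, 1), 2), n = 10),
                 "positive semi-definite")
})
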