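test_that("proposal-SD adaptation implements the three-branch rule", {
  # inside the tolerance band: unchanged
  expect_equal(adapt_proposal_sd(1, 0.45), 1)
  expect_equal(adapt_proposal_sd(2.5, 0.54), 2.5)
  expect_equal(adapt_proposal_sd(2.5, 0.36), 2.5)
  # above the band: inflate by 2 - (1 - r*)/(1 - r)
  expect_equal(adapt_proposal_sd(1, 0.90), 2 - 0.1 / 0.55)
  expect_equal(adapt_proposal_sd(1, 0.90), 1.818182, tolerance = 1e-6)
  # below the band: divide by 2 - r*/r
  expect_equal(adapt_proposal_sd(1, 0.20), 1 / (2 - 0.2 / 0.45))
  expect_equal(2 - 0.2 / 0.45, 1.555556, tolerance = 1e-6)
  expect_lt(adapt_proposal_sd(1, 0.20), 1)
  # vectorized and positive
  out <- adapt_proposal_sd(c(1, 1, 1), c(0.9, 0.45, 0.2))
  expect_true(all(out > 0))
  expect_equal(out[2], 1)
})

test_that("the component MH ratio matches the grid posterior density ratio", {
  spec <- equal_spec()
  mom <- idealized_moments(0.7, 0.5, 30, spec = spec)
  priors <- prior_config(spec, mu_rho = 0.2, nu_rho = 2,
                         mu_lambda = 0.6, nu_lambda = 1)
  g <- build_grid(mom, priors, spec, step = 0.01)
  j <- 40 # a lambda cell
  i1 <- 120; i2 <- 150
  theta_vec <- c(g$lambda_axis[j], g$rho_axis[i2])
  lr <- mh_log_ratio(g$rho_axis[i1], g$rho_axis[i2], d = 2, theta_vec,
                     mom, spec, priors)
  expect_equal(lr, g$log_density[i1, j] - g$log_density[i2, j],
               tolerance = 1e-8)
  # identity proposal: always accepted
  expect_equal(mh_log_ratio(0.3, 0.3, 2, theta_vec, mom, spec, priors), 0)
  # flat priors cancel: ratio reduces to the likelihood difference
  flat <- uniform_priors(spec)
  ll <- function(r) log_likelihood(cfa_parameters(theta_vec[1], r, spec = spec),
                                   mom, spec)
  expect_equal(mh_log_ratio(0.4, 0.1, 2, theta_vec, mom, spec, flat),
               ll(0.4) - ll(0.1), tolerance = 1e-10)
  # out-of-support proposal is rejected outright
  expect_equal(mh_log_ratio(1.2, 0.1, 2, theta_vec, mom, spec, flat), -Inf)
})

test_that("chains are reproducible and stay inside the admissible box", {
  spec <- two_factor_spec()
  set.seed(1)
  x <- gen_normal(cfa_parameters(0.5, 0.3, spec = spec), spec, 30)
  mom <- moments_from_data(x)
  cfg <- chain_config(iters = 600, burnin = 300, seed = 99)
  ch1 <- run_chain(mom, spec, config = cfg)
  ch2 <- run_chain(mom, spec, config = cfg)
  expect_identical(ch1$draws, ch2$draws)
  eps <- spec$epsilon
  lam <- ch1$draws[, 1:6]
  expect_true(all(lam > eps - 1e-12 & lam < 1 - eps + 1e-12))
  expect_true(all(abs(ch1$draws[, "rho"]) < 1 - eps + 1e-12))
  expect_true(all(ch1$draws[, 8:13] > 0))
  expect_true(all(ch1$acceptance >= 0 & ch1$acceptance <= 1))
})

test_that("chain summaries converge to the grid-integration oracle", {
  spec <- equal_spec()
  mom <- idealized_moments(0.7, 0.5, 30, spec = spec)
  ge <- grid_estimates(mom, spec = spec)
  ch <- run_chain(mom, spec, uniform_priors(spec),
                  chain_config(iters = 30000, burnin = 5000, seed = 17))
  pe <- chain_point_estimates(ch)
  expect_equal(unname(pe$eap["rho"]), unname(ge["eap"]), tolerance = 0.015)
  expect_equal(unname(pe$med["rho"]), unname(ge["med"]), tolerance = 0.015)
})

test_that("a near-degenerate prior concentrates the posterior at its guess", {
  spec <- two_factor_spec()
  mom <- idealized_moments(0.7, 0.5, 30)
  strong <- prior_config(spec, mu_rho = 0.3, nu_rho = 1e6)
  ch <- run_chain(mom, spec, strong,
                  chain_config(iters = 3000, burnin = 1500, seed = 5))
  expect_lt(stats::sd(ch$draws[, "rho"]), 0.01)
  expect_equal(mean(ch$draws[, "rho"]), 0.3, tolerance = 0.01)
})

test_that("point estimates behave on degenerate and skewed chains", {
  # constant chain: every summary collapses to the constant
  const <- list(draws = matrix(0.42, 100, 1, dimnames = list(NULL, "rho")),
                logpost = rep(-1, 100))
  pe <- chain_point_estimates(const)
  expect_equal(unname(pe$eap), 0.42)
  expect_equal(unname(pe$med), 0.42)
  expect_equal(unname(pe$map), 0.42)
  expect_equal(unname(pe$bci), matrix(0.42, 2, 1))
  expect_equal(unname(pe$pml_mcmc), 0.42)

  # right-skewed draws: mode < median < mean
  set.seed(13)
  b <- stats::rbeta(50000, 2, 5)
  sk <- list(draws = matrix(b, ncol = 1, dimnames = list(NULL, "x")),
             logpost = rep(0, length(b)))
  ps <- chain_point_estimates(sk)
  expect_lt(ps$map, ps$med)
  expect_lt(ps$med, ps$eap)
  expect_lt(abs(unname(ps$map) - 1 / 5), 0.05) # Beta(2,5) mode

  # symmetric unimodal draws: all three roughly agree
  z <- matrix(stats::rnorm(50000, 3, 1), ncol = 1, dimnames = list(NULL, "x"))
  pz <- chain_point_estimates(list(draws = z, logpost = rep(0, nrow(z))))
  expect_equal(unname(pz$eap), unname(pz$med), tolerance = 0.03)
  expect_equal(unname(pz$eap), unname(pz$map), tolerance = 0.06)
})

test_that("the retained draw maximizing the posterior tracks the joint mode", {
  spec <- equal_spec()
  mom <- idealized_moments(0.7, 0.5, 100, spec = spec)
  ch <- run_chain(mom, spec, config = chain_config(iters = 20000,
                                                   burnin = 4000, seed = 23))
  pe <- chain_point_estimates(ch)
  expect_equal(unname(pe$pml_mcmc["rho"]), 0.7, tolerance = 0.05)
})

test_that("diagnostics distinguish mixing from non-mixing chains", {
  set.seed(3)
  # independent draws: PSR near 1, ESS near the chain length
  iid <- matrix(stats::rnorm(20000), ncol = 2,
                dimnames = list(NULL, c("a", "b")))
  d <- mcmc_diagnostics(iid)
  expect_true(all(d$psr > 0.99 & d$psr < 1.05))
  expect_true(all(abs(d$ess / 10000 - 1) < 0.2))
  # two stuck chains at different constants
  d2 <- mcmc_diagnostics(list(matrix(0, 100, 1), matrix(1, 100, 1)))
  expect_true(is.infinite(d2$psr) || d2$psr > 10)
  # AR(1) with phi = 0.5: ESS/T near (1 - phi)/(1 + phi) = 1/3
  ar <- matrix(stats::filter(stats::rnorm(50000), 0.5, method = "recursive"),
               ncol = 1)
  d3 <- mcmc_diagnostics(ar)
  expect_lt(abs(d3$ess / 50000 - 1 / 3), 0.1 / 3)
  # too-short chains
  expect_warning(out <- mcmc_diagnostics(matrix(stats::rnorm(10), ncol = 1)),
                 "too short")
  expect_null(out)
})
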