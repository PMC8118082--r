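test_that("all estimators recover the truth from saturated moments", {
  spec <- two_factor_spec()
  mom <- idealized_moments(0.7, 0.5, 100)
  truth <- c(rep(0.5, 6), 0.7, rep(1, 6))

  f_pml <- fit_pml(mom, spec)
  expect_equal(unname(f_pml$point), truth, tolerance = 1e-4)
  expect_equal(f_pml$status, "converged")

  f_cml <- fit_ml_constrained(mom, spec)
  expect_equal(unname(f_cml$point), truth, tolerance = 1e-4)

  f_ml <- fit_ml_unconstrained(mom, spec)
  expect_equal(f_ml$unstd$rho, 0.7, tolerance = 1e-4)
  expect_true(f_ml$admissible)

  f_uls <- fit_uls(mom, spec)
  expect_equal(unname(f_uls$point), truth, tolerance = 1e-3)
  expect_lt(f_uls$discrepancy, 1e-10)
})

test_that("penalized ML with uniform priors equals constrained ML", {
  spec <- two_factor_spec()
  set.seed(42)
  for (i in 1:10) {
    th <- cfa_parameters(stats::runif(1, 0.3, 0.7), stats::runif(1, -0.8, 0.8),
                         spec = spec)
    x <- gen_normal(th, spec, 30)
    mom <- moments_from_data(x)
    fp <- suppressWarnings(fit_pml(mom, spec, uniform_priors(spec), se = FALSE))
    fc <- suppressWarnings(fit_ml_constrained(mom, spec, se = FALSE))
    expect_lt(max(abs(fp$point - fc$point)), 1e-5)
  }
})

test_that("an informative correlation prior pulls the PML toward its guess", {
  spec <- two_factor_spec()
  set.seed(8)
  x <- gen_normal(cfa_parameters(0.5, 0.7, spec = spec), spec, 40)
  mom <- moments_from_data(x)
  rho_flat <- fit_pml(mom, spec, se = FALSE)$point[7]
  mu <- 0.3
  rho_prev <- rho_flat
  for (nu in c(1, 3, 10, 100)) {
    pr <- prior_config(spec, mu_rho = mu, nu_rho = nu)
    rho_nu <- fit_pml(mom, spec, pr, se = FALSE)$point[7]
    # between the flat-prior estimate and the prior guess, moving monotonically
    expect_true(rho_nu <= rho_prev + 1e-6 && rho_nu >= mu - 1e-6)
    rho_prev <- rho_nu
  }
  # prior dominance
  strong <- prior_config(spec, mu_rho = 0.3, nu_rho = 1e6)
  expect_equal(unname(fit_pml(mom, spec, strong, se = FALSE)$point[7]), 0.3,
               tolerance = 1e-3)
})

test_that("ULS matches an exhaustive grid search on the two-parameter model", {
  spec <- equal_spec()
  set.seed(21)
  x <- gen_normal(cfa_parameters(0.5, 0.4, spec = spec), spec, 50)
  mom <- moments_from_data(x)
  f <- fit_uls(mom, spec, starts = 3)
  # brute-force grid oracle
  lams <- seq(0.05, 0.95, by = 0.005)
  rhos <- seq(-0.95, 0.95, by = 0.005)
  disc <- function(r, l) {
    th <- cfa_parameters(l, r, spec = spec)
    sum((mom$cov - implied_covariance(th, spec))^2)
  }
  vals <- outer(rhos, lams, Vectorize(disc))
  best <- arrayInd(which.min(vals), dim(vals))
  expect_lt(abs(unname(f$point["rho"]) - rhos[best[1]]), 0.006)
  expect_lt(abs(unname(f$point["lambda"]) - lams[best[2]]), 0.006)
  expect_lte(f$discrepancy, min(vals) + 1e-10)
})

test_that("observed information matches classical and refined oracles", {
  # Gaussian-mean toy model: SE must equal sigma/sqrt(n)
  set.seed(31)
  n <- 50; s <- 2
  x <- stats::rnorm(n, 1, s)
  ll <- function(m) sum(stats::dnorm(x, m, s, log = TRUE))
  se <- observed_information_se(c(mu = mean(x)), loglik_fn = ll)
  expect_equal(unname(se), s / sqrt(n), tolerance = 1e-6)

  # CFA Hessian vs a Richardson-extrapolated second-difference oracle
  spec <- two_factor_spec()
  mom <- idealized_moments(0.6, 0.5, 80)
  v <- c(rep(0.45, 6), 0.5, rep(1.05, 6))
  f <- function(z) smallcfa:::ll_bounded(z, spec, mom)
  H1 <- smallcfa:::num_hessian(f, v, h = rep(2e-4, 13))
  H2 <- smallcfa:::num_hessian(f, v, h = rep(1e-4, 13))
  H_rich <- (4 * H2 - H1) / 3
  H <- smallcfa:::num_hessian(f, v)
  expect_equal(H / max(abs(H_rich)), H_rich / max(abs(H_rich)),
               tolerance = 1e-4)
})

test_that("a seeded small-sample draw reproduces the inadmissible-ML fixture", {
  # fixture located by forward seed scan: true rho = 0.9, lambda = 0.5, n = 30
  spec <- two_factor_spec()
  th <- cfa_parameters(0.5, 0.9, spec = spec)
  x <- gen_normal(th, spec, 30, seed = 7)
  mom <- moments_from_data(x)
  fu <- suppressWarnings(fit_ml_unconstrained(mom, spec))
  expect_equal(fu$status, "converged")
  expect_false(fu$admissible)
  expect_gt(fu$unstd$rho, 1)
  fc <- suppressWarnings(fit_ml_constrained(mom, spec))
  expect_true(fc$at_boundary)
  expect_equal(unname(fc$point["rho"]), 1 - spec$epsilon, tolerance = 1e-6)
  # SEs at the boundary stay finite thanks to the pull-in
  expect_true(is.null(fc$se) || all(is.finite(fc$se)))
})

test_that("unconstrained and constrained ML coincide on interior optima", {
  spec <- two_factor_spec()
  set.seed(55)
  hits <- 0
  for (i in 1:10) {
    x <- gen_normal(cfa_parameters(0.5, 0.3, spec = spec), spec, 200)
    mom <- moments_from_data(x)
    fu <- suppressWarnings(fit_ml_unconstrained(mom, spec, se = FALSE))
    fc <- suppressWarnings(fit_ml_constrained(mom, spec, se = FALSE))
    if (fu$status == "converged" && fu$admissible && !fc$at_boundary) {
      hits <- hits + 1
      expect_lt(abs(unname(fu$unstd$rho) - unname(fc$point["rho"])), 1e-4)
    }
  }
  expect_gt(hits, 5) # large-n interior optima should dominate
})

test_that("Huber-type moments behave like classical moments on clean data", {
  spec <- two_factor_spec()
  th <- cfa_parameters(0.5, 0.5, spec = spec)
  x <- gen_normal(th, spec, 1e4, seed = 2)
  hm <- huber_moments(x)
  cl <- moments_from_data(x)
  expect_lt(max(abs(hm$cov - cl$cov)), 0.02)
  w <- attr(hm, "weights")
  expect_true(all(w > 0 & w <= 1))
  # weights are non-increasing in Mahalanobis distance
  d <- sqrt(stats::mahalanobis(x, hm$mean, hm$cov))
  ord <- order(d)
  expect_true(all(diff(w[ord]) <= 1e-12))
})

test_that("Huber-type moments resist gross contamination", {
  spec <- two_factor_spec()
  th <- cfa_parameters(0.5, 0.5, spec = spec)
  truth <- implied_covariance(th, spec)
  x <- gen_normal(th, spec, 2000, seed = 3)
  x[1:100, ] <- x[1:100, ] + 8 # 5% gross outliers
  err_classical <- norm(moments_from_data(x)$cov - truth, "F")
  err_huber <- norm(huber_moments(x)$cov - truth, "F")
  expect_lt(err_huber, err_classical)
})
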