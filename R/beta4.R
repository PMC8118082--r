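#' Four-parameter beta prior distribution
#'
#' A beta distribution stretched onto an arbitrary bounded interval
#' `[l, u]`: if `X ~ Beta(a, b)` then `Y = l + (u - l) X ~ Beta4(a, b, l, u)`.
#' Alongside the shape parameterization, the object carries the elicitation
#' parameterization used throughout this package: a prior guess
#' `mu = l + (u - l) a / (a + b)` and a prior sample size `nu = a + b - 2`
#' (so `nu = 0` with `mu` at the interval midpoint is the uniform prior).
#'
#' @param a,b Positive shape parameters.
#' @param l,u Lower and upper support bounds (`l < u`).
#' @return Object of class `"beta4_prior"` with fields `a`, `b`, `l`, `u`,
#'   `mu`, `nu`.
#' @seealso [beta4_from_mu_nu()] for the elicitation constructor.
#' @examples
#' beta4_prior(2, 2, -1, 1)
#' @export
beta4_prior <- function(a, b, l = 0, u = 1) {
  if (a <= 0 || b <= 0) stop("shape parameters must be positive")
  if (l >= u) stop("need l < u")
  structure(
    list(a = a, b = b, l = l, u = u,
         mu = l + (u - l) * a / (a + b),
         nu = a + b - 2),
    class = "beta4_prior"
  )
}

#' @export
print.beta4_prior <- function(x, ...) {
  cat(sprintf("Beta4 prior on [%g, %g]: a = %g, b = %g (mu = %g, nu = %g)\n",
              x$l, x$u, x$a, x$b, x$mu, x$nu))
  invisible(x)
}

#' Construct a four-parameter beta prior from a prior guess and sample size
#'
#' Converts the elicitation parameterization `(mu, nu)` into shapes via
#' `a = (nu + 2)(mu - l)/(u - l)` and `b = (nu + 2)(u - mu)/(u - l)`.
#' `nu = 0` with `mu` at the midpoint of `[l, u]` gives the uniform
#' distribution; increasing `nu` concentrates mass around `mu`.
#'
#' @param mu Prior guess, strictly inside `(l, u)`.
#' @param nu Prior sample size (>= 0).
#' @param l,u Support bounds.
#' @return A [beta4_prior()].
#' @examples
#' beta4_from_mu_nu(0.5, 0, 0, 1) # uniform: a = b = 1
#' @export
beta4_from_mu_nu <- function(mu, nu, l = 0, u = 1) {
  if (mu <= l || mu >= u) stop("mu must lie strictly inside (l, u)")
  if (nu < 0) stop("nu must be >= 0")
  a <- (nu + 2) * (mu - l) / (u - l)
  b <- (nu + 2) * (u - mu) / (u - l)
  beta4_prior(a, b, l, u)
}

#' Log-density of a four-parameter beta prior
#'
#' Total function: returns `-Inf` outside the support `[l, u]`; finite inside
#' the open interval for all valid shapes (endpoints follow the limiting
#' density, e.g. `-Inf` at `l` when `a > 1`).
#'
#' @param x Numeric vector of evaluation points.
#' @param prior A [beta4_prior()].
#' @return Vector of log-densities.
#' @examples
#' beta4_logpdf(0, beta4_prior(1, 1, -1, 1)) # log(0.5)
#' @export
beta4_logpdf <- function(x, prior) {
  z <- (x - prior$l) / (prior$u - prior$l)
  out <- stats::dbeta(z, prior$a, prior$b, log = TRUE) - log(prior$u - prior$l)
  out[x < prior$l | x > prior$u] <- -Inf
  out
}

#' Density of a four-parameter beta prior
#' @inheritParams beta4_logpdf
#' @return Vector of densities (0 outside the support).
#' @export
beta4_pdf <- function(x, prior) exp(beta4_logpdf(x, prior))

#' Random draws from a four-parameter beta prior
#' @param n Number of draws.
#' @param prior A [beta4_prior()].
#' @return Numeric vector of length `n`.
#' @export
beta4_sample <- function(n, prior) {
  prior$l + (prior$u - prior$l) * stats::rbeta(n, prior$a, prior$b)
}

#' Mean and variance of a four-parameter beta prior
#'
#' The mean is `l + (u - l) a/(a + b)`; the variance is the unit-interval beta
#' variance scaled by `(u - l)^2`. On `[0, 1]` the variance equals
#' `mu (1 - mu) / (nu + 3)`.
#'
#' @param prior A [beta4_prior()].
#' @return List with `mean` and `variance`.
#' @export
beta4_mean_var <- function(prior) {
  a <- prior$a; b <- prior$b
  m01 <- a / (a + b)
  v01 <- a * b / ((a + b)^2 * (a + b + 1))
  list(mean = prior$l + (prior$u - prior$l) * m01,
       variance = (prior$u - prior$l)^2 * v01)
}

#' Per-parameter prior configuration for the bounded CFA parameterization
#'
#' Assigns a four-parameter beta prior to every standardized loading (support
#' `[epsilon, 1 - epsilon]`) and to the latent correlation (support
#' `[-1 + epsilon, 1 - epsilon]`), and an improper constant prior to every
#' indicator standard deviation. The sigma prior is flat on the sigma scale
#' (not log sigma); it contributes 0 to the log-prior on `sigma > 0`.
#'
#' @param spec A [cfa_model_spec()] (provides `epsilon` and dimensions).
#' @param mu_lambda,nu_lambda Prior guess and prior sample size for each
#'   standardized loading. `nu_lambda = 0` with `mu_lambda = 0.5` is the
#'   uniform prior on the loading interval.
#' @param mu_rho,nu_rho Prior guess and prior sample size for the latent
#'   correlation. `nu_rho = 0` with `mu_rho = 0` is the uniform prior on the
#'   correlation interval.
#' @return Object of class `"prior_config"` with `lambda` and `rho`
#'   [beta4_prior()] entries, the `sigma` prior tag `"flat"`, and a `uniform`
#'   flag (TRUE when both beta4 components are uniform).
#' @examples
#' uniform_priors(cfa_model_spec())
#' prior_config(cfa_model_spec(), mu_rho = 0.3, nu_rho = 3)
#' @export
prior_config <- function(spec = cfa_model_spec(),
                         mu_lambda = 0.5, nu_lambda = 0,
                         mu_rho = 0, nu_rho = 0) {
  eps <- spec$epsilon
  lambda <- beta4_from_mu_nu(mu_lambda, nu_lambda, eps, 1 - eps)
  rho <- beta4_from_mu_nu(mu_rho, nu_rho, -1 + eps, 1 - eps)
  uniform <- nu_lambda == 0 && mu_lambda == 0.5 && nu_rho == 0 && mu_rho == 0
  structure(list(lambda = lambda, rho = rho, sigma = "flat", uniform = uniform),
            class = "prior_config")
}

#' @rdname prior_config
#' @export
uniform_priors <- function(spec = cfa_model_spec()) prior_config(spec)

#' @export
print.prior_config <- function(x, ...) {
  cat("Prior configuration\n")
  cat(sprintf("  loadings:    Beta4(mu = %g, nu = %g) on [%g, %g]\n",
              x$lambda$mu, x$lambda$nu, x$lambda$l, x$lambda$u))
  cat(sprintf("  correlation: Beta4(mu = %g, nu = %g) on [%g, %g]\n",
              x$rho$mu, x$rho$nu, x$rho$l, x$rho$u))
  cat("  indicator SDs: improper flat prior on sigma > 0\n")
  invisible(x)
}

#' Joint log-prior of a bounded parameter vector
#'
#' Sums the four-parameter beta log-densities over the standardized loadings
#' and the latent correlation; the improper flat priors on the indicator
#' standard deviations contribute 0 for `sigma > 0` and `-Inf` otherwise.
#'
#' @param theta A [cfa_parameters()] object.
#' @param config A [prior_config()].
#' @return Scalar log-prior (`-Inf` when any parameter is outside its
#'   prior support).
#' @export
log_prior <- function(theta, config) {
  lp <- sum(beta4_logpdf(theta$loadings, config$lambda)) +
    beta4_logpdf(theta$rho, config$rho)
  if (any(theta$sds <= 0)) lp <- -Inf
  lp
}

#' Materialize the crossed prior grid of the simulation studies
#'
#' Builds the 5 x 7 = 35 prior configurations crossing loading priors
#' (uniform; mu_lambda in \{0.5, 0.8\} with nu_lambda in \{1, 3\}) with
#' correlation priors (uniform; mu_rho in \{0.2, 0.5, 0.8\} with
#' nu_rho in \{1, 3\}).
#'
#' @param spec A [cfa_model_spec()].
#' @return A data frame with columns `mu_lambda`, `nu_lambda`, `mu_rho`,
#'   `nu_rho` and a list-column `config` of [prior_config()] objects.
#' @export
prior_grid <- function(spec = cfa_model_spec()) {
  lam <- rbind(
    data.frame(mu_lambda = 0.5, nu_lambda = 0),
    expand.grid(mu_lambda = c(0.5, 0.8), nu_lambda = c(1, 3))
  )
  rho <- rbind(
    data.frame(mu_rho = 0, nu_rho = 0),
    expand.grid(mu_rho = c(0.2, 0.5, 0.8), nu_rho = c(1, 3))
  )
  grid <- merge(lam, rho, by = NULL)
  grid$config <- lapply(seq_len(nrow(grid)), function(i) {
    prior_config(spec,
                 mu_lambda = grid$mu_lambda[i], nu_lambda = grid$nu_lambda[i],
                 mu_rho = grid$mu_rho[i], nu_rho = grid$nu_rho[i])
  })
  grid
}
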