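# Deterministic 2-D grid-integration posterior for the equal-loading
# two-factor model with fixed indicator SDs. Only (rho, lambda) are free, so
# the joint posterior can be evaluated exactly (up to grid resolution) and
# serves both as the engine of the illustrative study and as the oracle
# against which the MCMC sampler is checked.
#
# The implied covariance for this model is low-rank:
#   Sigma = (1 - lambda^2) I_p + lambda^2 (u1 u1' + u2 u2') +
#           lambda^2 rho (u1 u2' + u2 u1'),
# with u1, u2 the indicator-membership vectors of the two factors. The
# determinant lemma and the Woodbury identity reduce log|Sigma| and
# tr(Sigma^{-1} S) to 2x2 algebra, so the whole grid is evaluated with
# vectorized arithmetic; the sufficient statistics enter only through tr(S)
# and the three block sums of S. This closed form is cross-checked against
# the generic likelihood in the test suite.

# Rep-independent coefficient arrays over the (rho, lambda) grid:
#   loglik = -(n/2) (p log 2pi + logdet + c0*tr(S) + c11*g11 + 2 c12*g12 +
#            c22*g22)
# where g11, g22, g12 are the within/cross-factor block sums of S.
grid_coeffs <- function(rho_axis, lambda_axis, k1, k2) {
  p <- k1 + k2
  nr <- length(rho_axis)
  nl <- length(lambda_axis)
  lam2 <- matrix(lambda_axis^2, nr, nl, byrow = TRUE)
  rho <- matrix(rho_axis, nr, nl)
  a <- 1 - lam2
  t1 <- k1 * lam2 / a
  t2 <- k2 * lam2 / a
  logdet <- p * log(a) + log((1 + t1) * (1 + t2) - t1 * t2 * rho^2)
  alpha <- 1 / (lam2 * (1 - rho^2))
  d1 <- alpha + k1 / a
  d2 <- alpha + k2 / a
  detD <- d1 * d2 - (alpha * rho)^2
  W11 <- d2 / detD
  W22 <- d1 / detD
  W12 <- alpha * rho / detD
  list(p = p, logdet = logdet,
       c0 = 1 / a,
       c11 = -W11 / a^2, c12 = -W12 / a^2, c22 = -W22 / a^2)
}

# Block sums of S for factor sizes k1, k2 (S already on the standardized
# scale, i.e. rescaled by the fixed indicator SDs).
block_sums <- function(S, k1, k2) {
  i1 <- seq_len(k1)
  i2 <- k1 + seq_len(k2)
  list(tr = sum(diag(S)),
       g11 = sum(S[i1, i1]), g22 = sum(S[i2, i2]), g12 = sum(S[i1, i2]))
}

grid_loglik <- function(coef, bs, n) {
  tr <- coef$c0 * bs$tr + coef$c11 * bs$g11 + 2 * coef$c12 * bs$g12 +
    coef$c22 * bs$g22
  -(n / 2) * (coef$p * log(2 * pi) + coef$logdet + tr)
}

#' Posterior of (rho, lambda) on a bivariate grid
#'
#' Evaluates the joint posterior of the latent correlation and the shared
#' standardized loading for the equal-loading two-factor model (indicator SDs
#' fixed, default 1) on a regular grid of cell midpoints, and normalizes it by
#' the rectangle rule. The log posterior is likelihood plus the two
#' four-parameter beta log-priors.
#'
#' @param moments A [sample_moments()] object.
#' @param priors A [prior_config()]; defaults to uniform priors.
#' @param spec An equal-loading [cfa_model_spec()] with `fixed_sigma` set
#'   (defaults to the six-indicator, two-factor model with unit SDs).
#' @param step Grid step used for both axes (default 0.002).
#' @return Object of class `"posterior_grid"` with `rho_axis`, `lambda_axis`
#'   (cell midpoints), `log_density` (unnormalized), `density` (normalized so
#'   that `sum(density) * h_rho * h_lambda == 1`), steps `h_rho`, `h_lambda`,
#'   and the inputs.
#' @examples
#' spec <- cfa_model_spec(equal_loadings = TRUE, fixed_sigma = rep(1, 6))
#' th <- cfa_parameters(0.5, 0.7, spec = spec)
#' mom <- sample_moments(implied_covariance(th, spec), n = 30)
#' g <- build_grid(mom, step = 0.01)
#' joint_mode(g)
#' @export
build_grid <- function(moments,
                       priors = NULL,
                       spec = cfa_model_spec(equal_loadings = TRUE,
                                             fixed_sigma = rep(1, 6)),
                       step = 0.002) {
  if (!spec$equal_loadings) stop("grid posterior requires an equal-loading spec")
  if (is.null(spec$fixed_sigma)) {
    stop("grid posterior requires fixed indicator SDs in the spec")
  }
  if (spec$m != 2) stop("grid posterior is defined for the two-factor model")
  if (is.null(priors)) priors <- uniform_priors(spec)
  eps <- spec$epsilon
  k <- tabulate(spec$loading_map, nbins = 2)
  if (is.unsorted(spec$loading_map)) {
    # the block-sum reduction needs indicators grouped by factor
    stop("order the indicators by factor for the grid posterior")
  }
  rho_axis <- grid_axis(-1 + eps, 1 - eps, step)
  lambda_axis <- grid_axis(eps, 1 - eps, step)
  # rescale S by the fixed SDs; constants dropped (normalized away)
  Sstar <- sweep(sweep(moments$cov, 1, spec$fixed_sigma, "/"),
                 2, spec$fixed_sigma, "/")
  coef <- grid_coeffs(rho_axis, lambda_axis, k[1], k[2])
  logd <- grid_loglik(coef, block_sums(Sstar, k[1], k[2]), moments$n)
  logd <- logd + matrix(beta4_logpdf(rho_axis, priors$rho),
                        length(rho_axis), length(lambda_axis)) +
    matrix(beta4_logpdf(lambda_axis, priors$lambda),
           length(rho_axis), length(lambda_axis), byrow = TRUE)
  logd[!is.finite(logd)] <- -Inf
  dens <- exp(logd - max(logd))
  Z <- sum(dens) * step * step
  structure(list(rho_axis = rho_axis, lambda_axis = lambda_axis,
                 log_density = logd, density = dens / Z,
                 h_rho = step, h_lambda = step,
                 priors = priors, n = moments$n),
            class = "posterior_grid")
}

# Cell midpoints covering [l, u] with cells of width <= step (the number of
# cells is rounded up so the support is covered exactly).
grid_axis <- function(l, u, step) {
  ncell <- ceiling((u - l) / step - 1e-9)
  h <- (u - l) / ncell
  seq(l + h / 2, u - h / 2, length.out = ncell)
}

#' @export
print.posterior_grid <- function(x, ...) {
  cat("Posterior grid:", length(x$rho_axis), "x", length(x$lambda_axis),
      "cells (rho x lambda), n =", x$n, "\n")
  jm <- joint_mode(x)
  cat(sprintf("  joint mode: rho = %.3f, lambda = %.3f\n", jm[1], jm[2]))
  invisible(x)
}

#' Marginal posterior of the latent correlation from a grid
#'
#' Integrates the normalized joint density over the loading axis by the
#' rectangle rule.
#'
#' @param grid A [build_grid()] result.
#' @return Object of class `"posterior_marginal"`: `x` (rho midpoints),
#'   `density` (integrates to 1 by the rectangle rule), `h` (step).
#' @export
marginal_rho <- function(grid) {
  d <- rowSums(grid$density) * grid$h_lambda
  structure(list(x = grid$rho_axis, density = d, h = grid$h_rho),
            class = "posterior_marginal")
}

#' Mean, median, and mode of a 1-D gridded density
#'
#' EAP is the rectangle-rule first moment; the median interpolates linearly
#' within the cell where the cumulative rectangle sum crosses 0.5; the mode is
#' the argmax cell midpoint refined by a local three-point parabola (ties
#' break to the lowest-index cell; no refinement at the boundary).
#'
#' @param marginal A [marginal_rho()] result (or any list with `x`, `density`,
#'   `h`).
#' @return Named vector with `eap`, `med`, `map`.
#' @export
marginal_point_estimates <- function(marginal) {
  x <- marginal$x
  d <- marginal$density
  h <- marginal$h
  eap <- sum(x * d) * h
  FF <- cumsum(d) * h
  i <- which(FF >= 0.5)[1]
  F_prev <- if (i > 1) FF[i - 1] else 0
  med <- (x[i] - h / 2) + h * (0.5 - F_prev) / (FF[i] - F_prev)
  j <- which.max(d)
  map <- x[j]
  if (j > 1 && j < length(d)) {
    den <- d[j - 1] - 2 * d[j] + d[j + 1]
    if (den < 0) map <- x[j] + h * (d[j - 1] - d[j + 1]) / (2 * den)
  }
  c(eap = eap, med = med, map = map)
}

#' Mode of the joint grid posterior
#'
#' Returns the (rho, lambda) cell with the highest posterior density (ties
#' break to the lowest-index cell), refined by a local parabola along each
#' axis. With uniform priors this is the penalized/constrained ML estimate up
#' to grid resolution.
#'
#' @param grid A [build_grid()] result.
#' @return Named vector `c(rho =, lambda =)`.
#' @export
joint_mode <- function(grid) {
  d <- grid$density
  idx <- which(d == max(d))[1]
  ij <- arrayInd(idx, dim(d))
  i <- ij[1]; j <- ij[2]
  rho <- parabolic_refine(grid$rho_axis, d[, j], i, grid$h_rho)
  lambda <- parabolic_refine(grid$lambda_axis, d[i, ], j, grid$h_lambda)
  c(rho = rho, lambda = lambda)
}

parabolic_refine <- function(x, d, j, h) {
  out <- x[j]
  if (j > 1 && j < length(d)) {
    den <- d[j - 1] - 2 * d[j] + d[j + 1]
    if (den < 0) out <- x[j] + h * (d[j - 1] - d[j + 1]) / (2 * den)
  }
  out
}

#' Grid-based point estimates of the latent correlation
#'
#' Convenience wrapper running [build_grid()], [marginal_rho()],
#' [marginal_point_estimates()] and [joint_mode()] in one call.
#'
#' @inheritParams build_grid
#' @return Named vector with `pml` (joint-mode rho), `map`, `med`, `eap`
#'   (marginal-posterior summaries of rho).
#' @examples
#' spec <- cfa_model_spec(equal_loadings = TRUE, fixed_sigma = rep(1, 6))
#' th <- cfa_parameters(0.5, 0.7, spec = spec)
#' mom <- sample_moments(implied_covariance(th, spec), n = 30)
#' grid_estimates(mom)
#' @export
grid_estimates <- function(moments, priors = NULL,
                           spec = cfa_model_spec(equal_loadings = TRUE,
                                                 fixed_sigma = rep(1, 6)),
                           step = 0.002) {
  g <- build_grid(moments, priors, spec, step)
  mp <- marginal_point_estimates(marginal_rho(g))
  jm <- joint_mode(g)
  c(pml = unname(jm["rho"]), map = unname(mp["map"]),
    med = unname(mp["med"]), eap = unname(mp["eap"]))
}

# Reusable engine for simulation studies: precomputes everything that does
# not depend on the data so that per-replication evaluation reduces to a few
# vectorized array operations.
grid_engine <- function(priors = NULL,
                        spec = cfa_model_spec(equal_loadings = TRUE,
                                              fixed_sigma = rep(1, 6)),
                        step = 0.002) {
  if (is.null(priors)) priors <- uniform_priors(spec)
  eps <- spec$epsilon
  k <- tabulate(spec$loading_map, nbins = 2)
  rho_axis <- grid_axis(-1 + eps, 1 - eps, step)
  lambda_axis <- grid_axis(eps, 1 - eps, step)
  coef <- grid_coeffs(rho_axis, lambda_axis, k[1], k[2])
  nr <- length(rho_axis); nl <- length(lambda_axis)
  log_prior_mat <- matrix(beta4_logpdf(rho_axis, priors$rho), nr, nl) +
    matrix(beta4_logpdf(lambda_axis, priors$lambda), nr, nl, byrow = TRUE)
  sig <- spec$fixed_sigma
  k1 <- k[1]; k2 <- k[2]
  h <- step
  function(moments) {
    Sstar <- sweep(sweep(moments$cov, 1, sig, "/"), 2, sig, "/")
    logd <- grid_loglik(coef, block_sums(Sstar, k1, k2), moments$n) +
      log_prior_mat
    dens <- exp(logd - max(logd))
    dens <- dens / (sum(dens) * h * h)
    m <- rowSums(dens) * h
    mp <- marginal_point_estimates(list(x = rho_axis, density = m, h = h))
    idx <- which(dens == max(dens))[1]
    ij <- arrayInd(idx, dim(dens))
    pml <- parabolic_refine(rho_axis, dens[, ij[2]], ij[1], h)
    c(pml = pml, mp)
  }
}
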