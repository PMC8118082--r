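#' Specify a confirmatory factor analysis model with bounded parameters
#'
#' Defines a simple-structure CFA model in the bounded parameterization: each
#' indicator loads on exactly one factor through a standardized loading
#' \eqn{\lambda_j \in (0, 1)}, factors have unit variance and correlate through
#' a correlation matrix, and each indicator has a free standard deviation
#' \eqn{\sigma_j > 0}. Loadings and correlations are kept a small offset
#' `epsilon` away from their natural boundaries, which keeps the likelihood and
#' its derivatives well defined at constrained optima.
#'
#' @param loading_map Integer vector of length `p` mapping each indicator to
#'   its factor (the map `m[j]`), e.g. `c(1, 1, 1, 2, 2, 2)`.
#' @param equal_loadings Logical; if `TRUE` all indicators share one
#'   standardized loading (the illustrative two-parameter model).
#' @param fixed_sigma Optional numeric vector of length `p`. When supplied, the
#'   indicator standard deviations are fixed at these values instead of being
#'   estimated (the illustrative model fixes them at 1).
#' @param epsilon Boundary offset; loadings live in
#'   `[epsilon, 1 - epsilon]` and correlations in `[-1 + epsilon, 1 - epsilon]`.
#'
#' @return An object of class `"cfa_model_spec"` with elements `p` (number of
#'   indicators), `m` (number of factors), `loading_map`, `equal_loadings`,
#'   `fixed_sigma`, `epsilon`, `loading_bounds`, and `correlation_bounds`.
#'
#' @examples
#' spec <- cfa_model_spec(c(1, 1, 1, 2, 2, 2))
#' spec
#' @export
cfa_model_spec <- function(loading_map = c(1, 1, 1, 2, 2, 2),
                           equal_loadings = FALSE,
                           fixed_sigma = NULL,
                           epsilon = 0.001) {
  loading_map <- as.integer(loading_map)
  p <- length(loading_map)
  m <- max(loading_map)
  if (epsilon <= 0 || epsilon >= 0.5) {
    stop("epsilon must be in (0, 0.5)")
  }
  if (!setequal(unique(loading_map), seq_len(m))) {
    stop("loading_map must use consecutive factor indices 1..m")
  }
  if (p < 2 * m) {
    stop("need at least two indicators per factor (p >= 2m)")
  }
  if (!is.null(fixed_sigma)) {
    fixed_sigma <- as.numeric(fixed_sigma)
    if (length(fixed_sigma) != p || any(fixed_sigma <= 0)) {
      stop("fixed_sigma must be a length-p vector of positive values")
    }
  }
  structure(
    list(
      p = p, m = m,
      loading_map = loading_map,
      equal_loadings = isTRUE(equal_loadings),
      fixed_sigma = fixed_sigma,
      epsilon = epsilon,
      loading_bounds = c(epsilon, 1 - epsilon),
      correlation_bounds = c(-1 + epsilon, 1 - epsilon)
    ),
    class = "cfa_model_spec"
  )
}

#' @export
print.cfa_model_spec <- function(x, ...) {
  cat("CFA model: ", x$p, " indicators, ", x$m, " factor(s)\n", sep = "")
  cat("  loading map:", paste(x$loading_map, collapse = " "), "\n")
  if (x$equal_loadings) cat("  equal loadings across indicators\n")
  if (!is.null(x$fixed_sigma)) {
    cat("  indicator SDs fixed at:", paste(format(x$fixed_sigma), collapse = " "), "\n")
  }
  cat("  epsilon:", x$epsilon, "\n")
  invisible(x)
}

#' Bundle a bounded parameter vector
#'
#' Collects standardized loadings, the latent correlation structure, and
#' indicator standard deviations into a validated parameter object for the
#' bounded parameterization `x_j = sigma_j (lambda_j eta_m[j] + eps_j)`.
#'
#' @param loadings Standardized loadings, one per indicator (values in (0, 1)),
#'   or a single value for an equal-loading model.
#' @param correlation Latent correlation `rho` for two factors, or an
#'   `m x m` correlation matrix for `m > 2` factors.
#' @param sds Indicator standard deviations (positive); default all 1.
#' @param spec A [cfa_model_spec()]; used to validate dimensions and expand an
#'   equal loading.
#'
#' @return An object of class `"cfa_parameters"` with elements `loadings`,
#'   `phi` (factor correlation matrix), `rho` (its off-diagonal when `m = 2`),
#'   and `sds`.
#' @examples
#' theta <- cfa_parameters(0.5, 0.7, spec = cfa_model_spec(rep(1:2, each = 3)))
#' @export
cfa_parameters <- function(loadings, correlation, sds = NULL,
                           spec = cfa_model_spec()) {
  p <- spec$p
  m <- spec$m
  if (length(loadings) == 1L) loadings <- rep(loadings, p)
  if (length(loadings) != p) stop("loadings must have length 1 or p")
  if (any(loadings <= 0) || any(loadings >= 1)) {
    stop("standardized loadings must lie strictly in (0, 1)")
  }
  if (is.matrix(correlation)) {
    phi <- correlation
    if (!all(dim(phi) == c(m, m))) stop("correlation matrix must be m x m")
    if (max(abs(phi - t(phi))) > 1e-12) stop("correlation matrix must be symmetric")
    if (any(abs(diag(phi) - 1) > 1e-12)) stop("correlation matrix needs unit diagonal")
    if (det(phi) <= 0) stop("correlation matrix must be positive definite")
    if (any(abs(phi[upper.tri(phi)]) >= 1)) stop("|correlations| must be < 1")
  } else {
    if (m != 2 && !(m == 1 && correlation == 0)) {
      if (m != 2) stop("scalar correlation requires a two-factor model")
    }
    if (abs(correlation) >= 1) stop("|rho| must be < 1")
    phi <- diag(m)
    if (m == 2) phi[1, 2] <- phi[2, 1] <- correlation
  }
  if (is.null(sds)) sds <- if (!is.null(spec$fixed_sigma)) spec$fixed_sigma else rep(1, p)
  if (length(sds) == 1L) sds <- rep(sds, p)
  if (length(sds) != p || any(sds <= 0)) stop("sds must be positive, length p")
  structure(
    list(
      loadings = as.numeric(loadings),
      phi = phi,
      rho = if (m == 2) phi[1, 2] else NA_real_,
      sds = as.numeric(sds)
    ),
    class = "cfa_parameters"
  )
}

#' @export
print.cfa_parameters <- function(x, ...) {
  cat("CFA parameters\n")
  cat("  loadings:", paste(format(x$loadings, digits = 3), collapse = " "), "\n")
  if (!is.na(x$rho)) cat("  latent correlation:", format(x$rho, digits = 3), "\n")
  cat("  indicator SDs:", paste(format(x$sds, digits = 3), collapse = " "), "\n")
  invisible(x)
}

#' Sufficient statistics for the marginal CFA likelihood
#'
#' Wraps the sample mean vector, sample covariance matrix and sample size. The
#' covariance matrix with divisor `n` (the maximum-likelihood version) is the
#' sufficient statistic for the covariance-structure likelihood, so all
#' estimators in this package consume these moments rather than raw data.
#'
#' @param cov p x p sample covariance matrix (symmetric).
#' @param n Sample size.
#' @param mean Optional length-p mean vector (the mean structure is saturated
#'   and does not enter the covariance-structure likelihood).
#'
#' @return Object of class `"sample_moments"` with `mean`, `cov`, `n`.
#' @seealso [moments_from_data()] to compute moments from a raw data matrix.
#' @export
sample_moments <- function(cov, n, mean = NULL) {
  cov <- as.matrix(cov)
  p <- nrow(cov)
  if (ncol(cov) != p) stop("cov must be square")
  if (max(abs(cov - t(cov))) > 1e-8 * max(1, max(abs(cov)))) {
    stop("cov must be symmetric")
  }
  cov <- (cov + t(cov)) / 2
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev))) {
    warning("sample covariance matrix is not positive semi-definite")
  } else if (min(ev) < 1e-10 * max(abs(ev))) {
    warning("sample covariance matrix is near-singular")
  }
  if (is.null(mean)) mean <- rep(0, p)
  if (length(mean) != p) stop("mean must have length p")
  if (n < 1) stop("n must be positive")
  structure(list(mean = as.numeric(mean), cov = cov, n = n),
            class = "sample_moments")
}

#' Compute sample moments from a raw data matrix
#'
#' Uses the divisor-`n` covariance matrix, matching the sufficient statistic of
#' the marginal likelihood.
#'
#' @param x n x p numeric data matrix (rows are observations).
#' @return A [sample_moments()] object.
#' @export
moments_from_data <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  xc <- sweep(x, 2, colMeans(x))
  sample_moments(crossprod(xc) / n, n = n, mean = colMeans(x))
}

#' Model-implied covariance matrix
#'
#' Assembles `Sigma(theta) = Lambda Phi Lambda' + Omega` in the bounded
#' parameterization: the standardized structure is scaled by the indicator
#' standard deviations, so diagonal entries are `sigma_j^2`, within-factor
#' off-diagonals are `sigma_i sigma_j lambda_i lambda_j`, and cross-factor
#' entries pick up the latent correlation.
#'
#' @param theta A [cfa_parameters()] object.
#' @param spec A [cfa_model_spec()].
#' @return The p x p model-implied covariance matrix.
#' @examples
#' spec <- cfa_model_spec()
#' implied_covariance(cfa_parameters(0.5, 0.7, spec = spec), spec)
#' @export
implied_covariance <- function(theta, spec = cfa_model_spec()) {
  p <- spec$p
  if (length(theta$loadings) != p || length(theta$sds) != p) {
    stop("parameter dimensions do not match the model spec")
  }
  lam <- theta$loadings
  map <- spec$loading_map
  phi_items <- theta$phi[map, map, drop = FALSE]
  R <- outer(lam, lam) * phi_items
  diag(R) <- 1
  sig <- outer(theta$sds, theta$sds) * R
  (sig + t(sig)) / 2
}

#' Marginal log-likelihood of a CFA model
#'
#' Evaluates the covariance-structure log-likelihood
#' \deqn{l(\theta) = -\frac{n}{2}\left[p \log 2\pi + \log|\Sigma(\theta)| +
#'   \mathrm{tr}(\Sigma(\theta)^{-1} S)\right],}
#' the multivariate-normal likelihood with the latent factors integrated out,
#' written as a function of the sufficient statistic `S`. The determinant and
#' trace use a Cholesky factorization rather than explicit inversion.
#'
#' @param theta A [cfa_parameters()] object.
#' @param moments A [sample_moments()] object.
#' @param spec A [cfa_model_spec()].
#' @param on_nonpd What to do when `Sigma(theta)` is not positive definite:
#'   `"-Inf"` (default; the contract used by samplers and optimizers, so such
#'   proposals are rejected) or `"error"`.
#' @return Scalar log-likelihood.
#' @examples
#' spec <- cfa_model_spec()
#' th <- cfa_parameters(0.5, 0.7, spec = spec)
#' mom <- sample_moments(implied_covariance(th, spec), n = 30)
#' log_likelihood(th, mom, spec)
#' @export
log_likelihood <- function(theta, moments, spec = cfa_model_spec(),
                           on_nonpd = c("-Inf", "error")) {
  on_nonpd <- match.arg(on_nonpd)
  sigma <- implied_covariance(theta, spec)
  loglik_sigma(sigma, moments$cov, moments$n, on_nonpd)
}

# Covariance-structure log-likelihood for an arbitrary implied matrix.
# Shared by the unstandardized (unconstrained-ML) parameterization.
loglik_sigma <- function(sigma, S, n, on_nonpd = "-Inf") {
  p <- nrow(sigma)
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ch)) {
    if (on_nonpd == "error") stop("implied covariance matrix is not positive definite")
    return(-Inf)
  }
  logdet <- 2 * sum(log(diag(ch)))
  # tr(Sigma^{-1} S) via two triangular solves
  tr <- sum(diag(backsolve(ch, forwardsolve(t(ch), S))))
  -(n / 2) * (p * log(2 * pi) + logdet + tr)
}

#' Sum-score reliability implied by a standardized loading
#'
#' For a tau-congeneric scale whose `I` items share the standardized loading
#' `lambda`, the reliability of the unit-weighted sum score is
#' \deqn{Rel_I = \frac{\lambda^2}{\lambda^2 + (1 - \lambda^2)/I}.}
#' This mapping is the practical route for eliciting loading priors: assuming a
#' plausible scale reliability pins down the per-item loading.
#'
#' @param lambda_std Standardized loading in (0, 1).
#' @param n_items Number of items `I` (>= 1).
#' @return Sum-score reliability in (0, 1); increasing in both arguments.
#' @examples
#' reliability_sum(0.58, 3) # ~0.60
#' @export
reliability_sum <- function(lambda_std, n_items) {
  if (any(lambda_std <= 0) || any(lambda_std >= 1)) {
    stop("lambda_std must lie strictly in (0, 1)")
  }
  if (any(n_items < 1)) stop("n_items must be >= 1")
  l2 <- lambda_std^2
  l2 / (l2 + (1 - l2) / n_items)
}

#' Standardized loading implied by a sum-score reliability
#'
#' Inverts [reliability_sum()]: the indicator-specific reliability is
#' `Rel_1 = Rel_I / (Rel_I + I (1 - Rel_I))` and the loading is its square
#' root.
#'
#' @param rel_sum Sum-score reliability in (0, 1).
#' @param n_items Number of items `I`.
#' @return The standardized loading `lambda` such that
#'   `reliability_sum(lambda, n_items) == rel_sum`.
#' @examples
#' loading_from_reliability(0.90, 3) # ~0.866
#' @export
loading_from_reliability <- function(rel_sum, n_items) {
  if (any(rel_sum <= 0) || any(rel_sum >= 1)) {
    stop("rel_sum must lie strictly in (0, 1)")
  }
  rel1 <- rel_sum / (rel_sum + n_items * (1 - rel_sum))
  sqrt(rel1)
}

#' Convert between unstandardized and standardized loading parameters
#'
#' In the unstandardized parameterization `x_j = lambda*_j eta + eps*_j` with
#' residual variance `omega*_jj`, the indicator variance is
#' `sigma_j^2 = lambda*_j^2 + omega*_jj` and the standardized loading is
#' `lambda_j = lambda*_j / sigma_j` (with standardized residual variance
#' `1 - lambda_j^2`).
#'
#' @param lambda_unstd Unstandardized loading(s).
#' @param resid_var Residual variance(s) `omega*_jj` (> 0).
#' @return A list with `sigma`, `lambda_std`, and `resid_std`
#'   (`1 - lambda_std^2`).
#' @seealso [unstandardize_parameters()] for the inverse map.
#' @examples
#' standardize_parameters(1, 3) # sigma = 2, lambda = 0.5
#' @export
standardize_parameters <- function(lambda_unstd, resid_var) {
  if (any(resid_var <= 0)) stop("residual variances must be positive")
  sigma <- sqrt(lambda_unstd^2 + resid_var)
  lambda_std <- lambda_unstd / sigma
  list(sigma = sigma, lambda_std = lambda_std, resid_std = 1 - lambda_std^2)
}

#' @rdname standardize_parameters
#' @param lambda_std Standardized loading(s) in (-1, 1).
#' @param sigma Indicator standard deviation(s) (> 0).
#' @export
unstandardize_parameters <- function(lambda_std, sigma) {
  if (any(sigma <= 0)) stop("sigma must be positive")
  if (any(abs(lambda_std) >= 1)) stop("|lambda_std| must be < 1")
  lambda_unstd <- lambda_std * sigma
  resid_var <- sigma^2 * (1 - lambda_std^2)
  list(lambda_unstd = lambda_unstd, resid_var = resid_var)
}
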