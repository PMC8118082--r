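# Deterministic estimators: unconstrained / constrained / penalized ML, ULS,
# observed-information standard errors, and Huber-type robust moment input.

# Box bounds for the canonical bounded parameter vector.
bounded_box <- function(spec, moments) {
  n_lam <- if (spec$equal_loadings) 1L else spec$p
  eps <- spec$epsilon
  sigma_free <- is.null(spec$fixed_sigma)
  lower <- c(rep(eps, n_lam), -1 + eps, if (sigma_free) rep(1e-6, spec$p))
  upper <- c(rep(1 - eps, n_lam), 1 - eps, if (sigma_free) rep(Inf, spec$p))
  list(lower = lower, upper = upper, n_lam = n_lam, sigma_free = sigma_free)
}

# Dispersed starting points: loadings 0.5 with rho in {-0.5, 0, 0.5}, plus
# loadings {0.25, 0.75} with rho 0; indicator SDs always from diag(S).
dispersed_starts <- function(spec, moments, n_starts = 5L) {
  n_lam <- if (spec$equal_loadings) 1L else spec$p
  sigma_free <- is.null(spec$fixed_sigma)
  sds <- unname(sqrt(diag(moments$cov)))
  base <- list(c(0.5, 0), c(0.5, -0.5), c(0.5, 0.5), c(0.25, 0), c(0.75, 0))
  lapply(base[seq_len(min(n_starts, 5L))], function(b) {
    c(rep(b[1], n_lam), b[2], if (sigma_free) sds)
  })
}

# Fast likelihood for the canonical bounded vector (C++ core).
ll_bounded <- function(v, spec, moments) {
  n_lam <- if (spec$equal_loadings) 1L else spec$p
  lam <- if (spec$equal_loadings) rep(v[1], spec$p) else v[seq_len(spec$p)]
  sds <- if (is.null(spec$fixed_sigma)) v[n_lam + 1L + seq_len(spec$p)] else spec$fixed_sigma
  cpp_loglik(lam, v[n_lam + 1L], sds, as.integer(spec$loading_map),
             moments$cov, moments$n)
}

# Log-prior for the canonical bounded vector.
lp_bounded <- function(v, spec, priors) {
  n_lam <- if (spec$equal_loadings) 1L else spec$p
  sum(beta4_logpdf(v[seq_len(n_lam)], priors$lambda)) +
    beta4_logpdf(v[n_lam + 1L], priors$rho)
}

# Shared bounded optimizer (quasi-Newton nlminb, multiple dispersed starts).
# `penalty` is an optional log-prior function of the canonical vector. The
# penalty enters relative to its value at a fixed interior reference point:
# the additive normalization constant of the prior then cancels exactly, so
# under uniform priors the penalized objective reduces bit-for-bit to the
# likelihood and the constrained-ML equivalence is exact rather than
# optimizer-tolerance-limited.
fit_bounded <- function(moments, spec, penalty = NULL, starts = 5L,
                        method = "cml", se = TRUE) {
  box <- bounded_box(spec, moments)
  pen0 <- 0
  if (!is.null(penalty)) {
    ref <- c(rep(0.5, box$n_lam), 0,
             if (box$sigma_free) unname(sqrt(diag(moments$cov))))
    pen0 <- penalty(ref)
  }
  neg_obj <- function(v) {
    val <- ll_bounded(v, spec, moments)
    if (!is.null(penalty)) val <- val + (penalty(v) - pen0)
    if (!is.finite(val)) return(1e10)
    -val
  }
  best <- NULL
  for (s in dispersed_starts(spec, moments, starts)) {
    opt <- tryCatch(
      stats::nlminb(s, neg_obj, lower = box$lower, upper = box$upper,
                    control = list(iter.max = 500, eval.max = 1000)),
      error = function(e) NULL
    )
    if (is.null(opt)) next
    opt$converged <- opt$convergence == 0
    if (is.null(best) ||
        (opt$converged && !best$converged) ||
        (opt$converged == best$converged && opt$objective < best$objective)) {
      best <- opt
    }
  }
  if (is.null(best)) {
    return(make_fit(rep(NA_real_, length(box$lower)), spec, moments, method,
                    converged = FALSE))
  }
  make_fit(best$par, spec, moments, method, converged = best$converged,
           box = box, compute_se = se)
}

make_fit <- function(v, spec, moments, method, converged, box = NULL,
                     admissible = TRUE, se = NULL, compute_se = TRUE,
                     extra = list()) {
  nm <- param_names(spec)
  at_boundary <- FALSE
  ll <- NA_real_
  if (!anyNA(v)) {
    names(v) <- nm
    if (!is.null(box)) {
      at_boundary <- any(abs(v - box$lower) < 1e-6 & is.finite(box$lower)) ||
        any(abs(v - box$upper) < 1e-6 & is.finite(box$upper))
    }
    ll <- ll_bounded(v, spec, moments)
    if (is.null(se) && compute_se) {
      se <- observed_information_se(v, moments, spec)
    }
  }
  ci <- if (!is.null(se)) rbind(lower = v - 1.96 * se, upper = v + 1.96 * se)
  structure(c(list(point = v, se = se, ci95 = ci,
                   status = if (converged) "converged" else "nonconverged",
                   admissible = admissible, at_boundary = at_boundary,
                   method = method, loglik = ll, spec = spec), extra),
            class = "cfa_fit")
}

#' @export
print.cfa_fit <- function(x, ...) {
  cat("CFA fit (", x$method, "): ", x$status,
      if (!x$admissible) ", inadmissible",
      if (x$at_boundary) ", at boundary", "\n", sep = "")
  tab <- data.frame(estimate = x$point)
  if (!is.null(x$se)) {
    tab$se <- x$se
    tab$ci_lower <- x$ci95["lower", ]
    tab$ci_upper <- x$ci95["upper", ]
  }
  print(round(tab, 4))
  cat("log-likelihood:", format(x$loglik), "\n")
  invisible(x)
}

#' Unconstrained maximum likelihood estimation
#'
#' Fits the CFA model in the unstandardized parameterization (free loadings
#' `lambda*_j`, free residual variances `omega_j`, factor variances fixed to
#' 1, free factor correlation) with no bounds, mirroring the default behavior
#' of standard SEM software. With small samples this estimator can fail to
#' converge or produce inadmissible solutions (|rho| > 1, negative residual
#' variances); both outcomes are flagged, never silently repaired.
#'
#' @param moments A [sample_moments()] object.
#' @param spec A [cfa_model_spec()] (free loadings, free SDs).
#' @param starts Number of starting points (default 1: the single standard
#'   start, which is what makes small-sample estimation problems visible).
#' @param se Compute observed-information standard errors (disable inside
#'   replication loops that only need point estimates).
#' @return A `"cfa_fit"` with the canonical bounded-scale summaries where
#'   defined: `point` holds the standardized loadings, `rho`, and implied
#'   indicator SDs; `unstd` holds the raw unstandardized solution; `admissible`
#'   is `FALSE` when `|rho| > 1`; `se_rho` is the observed-information SE of
#'   the factor correlation on the unstandardized scale.
#' @export
fit_ml_unconstrained <- function(moments, spec = cfa_model_spec(), starts = 1L,
                                 se = TRUE) {
  p <- spec$p
  map <- spec$loading_map
  sds <- unname(sqrt(diag(moments$cov)))
  neg_obj <- function(v) {
    lam_u <- v[seq_len(p)]
    phi <- v[p + 1L]
    omega <- v[p + 1L + seq_len(p)]
    Phi <- matrix(c(1, phi, phi, 1), 2, 2)
    L <- matrix(0, p, 2)
    L[cbind(seq_len(p), map)] <- lam_u
    sigma <- L %*% Phi %*% t(L) + diag(omega, p)
    val <- cpp_loglik_sigma(sigma, moments$cov, moments$n)
    if (!is.finite(val)) return(1e10)
    -val
  }
  start_list <- list(c(0.5 * sds, 0, 0.5 * diag(moments$cov)))
  if (starts > 1L) {
    start_list <- c(start_list, list(
      c(0.5 * sds, 0.5, 0.5 * diag(moments$cov)),
      c(0.5 * sds, -0.5, 0.5 * diag(moments$cov)),
      c(0.25 * sds, 0, 0.9 * diag(moments$cov)),
      c(0.75 * sds, 0, 0.3 * diag(moments$cov))
    )[seq_len(min(starts - 1L, 4L))])
  }
  best <- NULL
  for (s in start_list) {
    opt <- tryCatch(stats::nlminb(s, neg_obj), error = function(e) NULL)
    if (is.null(opt)) next
    opt$converged <- opt$convergence == 0
    if (is.null(best) ||
        (opt$converged && !best$converged) ||
        (opt$converged == best$converged && opt$objective < best$objective)) {
      best <- opt
    }
  }
  if (is.null(best)) stop("optimizer failed on every start")
  v <- best$par
  lam_u <- v[seq_len(p)]
  rho <- v[p + 1L]
  omega <- v[p + 1L + seq_len(p)]
  admissible <- abs(rho) <= 1
  # the standardized solution only exists when residual variances are positive
  std <- if (all(omega > 0)) standardize_parameters(lam_u, omega)
  point <- stats::setNames(
    c(if (!is.null(std)) std$lambda_std else rep(NA_real_, p), rho,
      if (!is.null(std)) std$sigma else rep(NA_real_, p)),
    param_names(cfa_model_spec(spec$loading_map))
  )
  # observed-information SE on the parameterization actually optimized
  se_rho <- NULL
  if (se) {
    H <- num_hessian(function(z) -neg_obj(z), v)
    se_rho <- tryCatch({
      V <- solve(-H)
      dg <- diag(V)
      if (any(dg <= 0)) NULL else sqrt(dg[p + 1L])
    }, error = function(e) NULL)
  }
  make_fit(point, cfa_model_spec(spec$loading_map), moments, "ml",
           converged = best$converged, admissible = admissible,
           se = NULL, compute_se = FALSE,
           extra = list(unstd = list(lambda_unstd = lam_u, rho = rho,
                                     resid_var = omega),
                        se_rho = se_rho))
}

#' Constrained maximum likelihood estimation
#'
#' Maximizes the marginal log-likelihood in the bounded parameterization
#' subject to box constraints: standardized loadings in
#' `[epsilon, 1 - epsilon]`, the latent correlation in
#' `[-1 + epsilon, 1 - epsilon]`, indicator SDs positive. Equivalent to
#' penalized ML with uniform priors on the admissible box.
#'
#' @inheritParams fit_ml_unconstrained
#' @param starts Number of dispersed starting points (default 5).
#' @inheritParams fit_ml_unconstrained
#' @return A `"cfa_fit"`; estimates always satisfy the bounds, and
#'   `at_boundary` flags solutions at the box edge.
#' @export
fit_ml_constrained <- function(moments, spec = cfa_model_spec(), starts = 5L,
                               se = TRUE) {
  fit_bounded(moments, spec, penalty = NULL, starts = starts, method = "cml",
              se = se)
}

#' Penalized maximum likelihood (mode of the joint posterior)
#'
#' Maximizes the log-posterior `l(theta) + log pi(theta)` over the bounded
#' parameterization by quasi-Newton optimization with dispersed starts. The
#' log-prior acts as a penalty pulling estimates toward the prior guesses;
#' with uniform priors the result equals constrained ML. Standard errors come
#' from the observed information of the likelihood part only (the prior is
#' used to stabilize estimation, not for uncertainty).
#'
#' @inheritParams fit_ml_constrained
#' @param priors A [prior_config()].
#' @return A `"cfa_fit"`.
#' @examples
#' spec <- cfa_model_spec()
#' th <- cfa_parameters(0.5, 0.7, spec = spec)
#' mom <- sample_moments(implied_covariance(th, spec), n = 30)
#' fit_pml(mom, spec)
#' @export
fit_pml <- function(moments, spec = cfa_model_spec(),
                    priors = uniform_priors(spec), starts = 5L, se = TRUE) {
  fit_bounded(moments, spec,
              penalty = function(v) lp_bounded(v, spec, priors),
              starts = starts, method = "pml", se = se)
}

#' Unweighted least squares estimation
#'
#' Minimizes the ULS discrepancy `tr((S - Sigma(theta))' (S - Sigma(theta)))`
#' over the bounded parameterization.
#'
#' @inheritParams fit_ml_constrained
#' @return A `"cfa_fit"`; the `discrepancy` element holds the minimized ULS
#'   criterion.
#' @export
fit_uls <- function(moments, spec = cfa_model_spec(), starts = 5L) {
  box <- bounded_box(spec, moments)
  S <- moments$cov
  neg_obj <- function(v) {
    theta <- theta_from_vec(v, spec)
    sum((S - implied_covariance(theta, spec))^2)
  }
  best <- NULL
  for (s in dispersed_starts(spec, moments, starts)) {
    opt <- tryCatch(
      stats::nlminb(s, neg_obj, lower = box$lower, upper = box$upper,
                    control = list(iter.max = 500, eval.max = 1000)),
      error = function(e) NULL
    )
    if (is.null(opt)) next
    opt$converged <- opt$convergence == 0
    if (is.null(best) ||
        (opt$converged && !best$converged) ||
        (opt$converged == best$converged && opt$objective < best$objective)) {
      best <- opt
    }
  }
  if (is.null(best)) stop("optimizer failed on every start")
  make_fit(best$par, spec, moments, "uls", converged = best$converged,
           box = box, extra = list(discrepancy = best$objective))
}

#' Observed-information standard errors
#'
#' Standard errors from the inverse negative Hessian of the log-likelihood
#' (central finite differences, symmetrized), evaluated at the estimate.
#' Estimates lying on a box boundary are pulled inward by `epsilon` before
#' differentiation so the Hessian is computed at an interior point.
#'
#' @param theta_hat Canonical bounded parameter vector at the optimum.
#' @param moments A [sample_moments()] object.
#' @param spec A [cfa_model_spec()].
#' @param loglik_fn Optional custom log-likelihood taking the parameter
#'   vector; defaults to the CFA marginal likelihood.
#' @return Named vector of standard errors, or `NULL` with a warning when the
#'   observed information is not invertible (or not positive definite).
#' @export
observed_information_se <- function(theta_hat, moments, spec = cfa_model_spec(),
                                    loglik_fn = NULL) {
  if (is.null(loglik_fn)) {
    box <- bounded_box(spec, moments)
    eps <- spec$epsilon
    theta_hat <- pmin(pmax(theta_hat, box$lower + eps), box$upper - eps)
    loglik_fn <- function(v) ll_bounded(v, spec, moments)
  }
  H <- num_hessian(loglik_fn, theta_hat)
  V <- tryCatch(solve(-H), error = function(e) NULL)
  if (is.null(V) || any(diag(V) <= 0)) {
    warning("observed information matrix is not positive definite; no SEs")
    return(NULL)
  }
  stats::setNames(sqrt(diag(V)), names(theta_hat))
}

# Central-difference Hessian, symmetrized.
num_hessian <- function(f, x, h = NULL) {
  q <- length(x)
  if (is.null(h)) h <- pmax(1e-4, 1e-4 * abs(x))
  H <- matrix(NA_real_, q, q)
  f0 <- f(x)
  for (i in seq_len(q)) {
    ei <- replace(numeric(q), i, h[i])
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h[i]^2
    if (i < q) {
      for (j in (i + 1):q) {
        ej <- replace(numeric(q), j, h[j])
        H[i, j] <- H[j, i] <-
          (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
          (4 * h[i] * h[j])
      }
    }
  }
  H
}

#' Huber-type robust means and covariances
#'
#' Iteratively reweighted M-estimates of the mean vector and covariance
#' matrix: observations are weighted by the Huber function of their
#' Mahalanobis distance, `w_i = min(1, k / d_i)` with
#' `k = sqrt(qchisq(prob, p))`. Means use weights `w_i`; the covariance uses
#' `w_i^2` with an empirical consistency rescaling (dividing by
#' `mean(w_i^2 d_i^2) / p`), so when no observation is downweighted the
#' estimates equal the classical divisor-n moments. The exact weight/tuning
#' variant is a documented, swappable choice.
#'
#' @param x n x p raw data matrix.
#' @param prob Probability cut defining the Huber threshold (default 0.95).
#' @param max_iter,tol Iteration controls for the reweighting fixed point.
#' @return A [sample_moments()] object with attributes `weights` (final
#'   per-observation weights in (0, 1]) and `iterations`.
#' @export
huber_moments <- function(x, prob = 0.95, max_iter = 100, tol = 1e-8) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  k <- sqrt(stats::qchisq(prob, df = p))
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  S <- crossprod(xc) / n
  w <- rep(1, n)
  it <- 0
  repeat {
    it <- it + 1
    d <- sqrt(pmax(stats::mahalanobis(x, mu, S), 0))
    w_new <- ifelse(d <= k, 1, k / pmax(d, .Machine$double.eps))
    mu_new <- colSums(x * w_new) / sum(w_new)
    xc <- sweep(x, 2, mu_new)
    S_raw <- crossprod(xc * w_new) / n
    kappa <- mean(w_new^2 * rowSums((xc %*% solve(S)) * xc)) / p
    S_new <- S_raw / kappa
    delta <- max(abs(S_new - S), abs(mu_new - mu))
    mu <- mu_new; S <- S_new; w <- w_new
    if (delta < tol) break
    if (it >= max_iter) {
      warning("Huber reweighting did not converge; returning last iterate")
      break
    }
  }
  out <- sample_moments(S, n = n, mean = mu)
  attr(out, "weights") <- w
  attr(out, "iterations") <- it
  out
}
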