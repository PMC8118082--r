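# Replication harness: runs a design cell (true parameters x sample size x
# prior configuration x distribution shape) for R replications and aggregates
# bias, empirical SD, RMSE, relative RMSE, coverage, and estimation-problem
# rates for the latent correlation.

#' Deterministic per-replication seed
#'
#' Hashes the base seed, cell index, and replication index into a 32-bit seed
#' so that any cell (and any single replication) can be rerun independently.
#'
#' @param base_seed Integer base seed of the study.
#' @param cell Cell index (>= 1).
#' @param rep Replication index (>= 1).
#' @return Integer seed in `[1, 2^31 - 1)`.
#' @export
rep_seed <- function(base_seed, cell, rep) {
  b <- as.numeric(base_seed) %% 50021
  as.integer((b * 1664525 + cell * 22695477 + rep * 69069) %% 2147483563) + 1L
}

#' Define a simulation design cell
#'
#' @param rho True latent correlation.
#' @param n Sample size per replication.
#' @param lambda True standardized loading (shared by all indicators).
#' @param reps Number of replications `R`.
#' @param engine `"grid"` (exact 2-D integration over the equal-loading model,
#'   the illustrative-study engine) or `"mcmc"` (adaptive
#'   Metropolis-within-Gibbs on the free-loading model, the main-study
#'   engine).
#' @param priors A [prior_config()] or `NULL` for uniform priors.
#' @param skew,ex_kurt Marginal skewness / excess kurtosis of the generated
#'   indicators (0/0 = normal).
#' @param base_seed Base seed of the study.
#' @param cell_id Cell index used in per-replication seeding.
#' @param step Grid step (grid engine).
#' @param chain A [chain_config()] (mcmc engine); its seed field is ignored in
#'   favor of the per-replication seed.
#' @param robust Use [huber_moments()] instead of classical moments.
#' @return List of class `"design_cell"`.
#' @export
design_cell <- function(rho, n, lambda = 0.5, reps = 1000,
                        engine = c("grid", "mcmc"), priors = NULL,
                        skew = 0, ex_kurt = 0, base_seed = 1, cell_id = 1L,
                        step = 0.002, chain = chain_config(), robust = FALSE) {
  engine <- match.arg(engine)
  structure(list(rho = rho, n = n, lambda = lambda, reps = reps,
                 engine = engine, priors = priors, skew = skew,
                 ex_kurt = ex_kurt, base_seed = base_seed,
                 cell_id = as.integer(cell_id), step = step, chain = chain,
                 robust = robust),
            class = "design_cell")
}

#' Run one simulation cell
#'
#' For each replication: generate data from the two-factor model, reduce to
#' sample moments, compute the latent-correlation point estimates of every
#' estimator, and (mcmc engine) the 95% intervals; then aggregate bias,
#' empirical SD, RMSE (`sqrt(bias^2 + var)` over the same replication set),
#' RMSE gain relative to flat-prior PML (100 = reference), and coverage.
#' Estimator failures are recorded, never abort the cell.
#'
#' @param cell A [design_cell()].
#' @return List of class `"cell_result"` with `estimates` (reps x estimator
#'   matrix of rho estimates), `metrics` (data frame: estimator, bias, sd,
#'   rmse, rmse_gain, coverage, n_covered), `failures`, and the cell.
#' @examples
#' cell <- design_cell(rho = 0.5, n = 30, reps = 20, engine = "grid",
#'                     base_seed = 7, step = 0.01)
#' run_cell(cell)$metrics
#' @export
run_cell <- function(cell) {
  if (cell$engine == "grid") run_cell_grid(cell) else run_cell_mcmc(cell)
}

gen_cell_data <- function(cell, spec_gen, theta, r) {
  seed <- rep_seed(cell$base_seed, cell$cell_id, r)
  if (cell$skew == 0 && cell$ex_kurt == 0) {
    gen_normal(theta, spec_gen, cell$n, seed = seed)
  } else {
    gen_nonnormal(theta, spec_gen, cell$n, cell$skew, cell$ex_kurt,
                  seed = seed)
  }
}

run_cell_grid <- function(cell) {
  spec_gen <- cfa_model_spec()
  theta <- cfa_parameters(cell$lambda, cell$rho, spec = spec_gen)
  spec_grid <- cfa_model_spec(equal_loadings = TRUE, fixed_sigma = rep(1, 6))
  priors <- if (is.null(cell$priors)) uniform_priors(spec_grid) else cell$priors
  engine <- grid_engine(priors, spec_grid, step = cell$step)
  est <- matrix(NA_real_, cell$reps, 4,
                dimnames = list(NULL, c("pml", "map", "med", "eap")))
  fail <- 0L
  for (r in seq_len(cell$reps)) {
    x <- gen_cell_data(cell, spec_gen, theta, r)
    mom <- if (cell$robust) huber_moments(x) else moments_from_data(x)
    e <- tryCatch(engine(mom), error = function(err) NULL)
    if (is.null(e)) fail <- fail + 1L else est[r, ] <- e[colnames(est)]
  }
  finish_cell(cell, est, intervals = NULL, failures = fail)
}

run_cell_mcmc <- function(cell) {
  spec <- cfa_model_spec()
  theta <- cfa_parameters(cell$lambda, cell$rho, spec = spec)
  priors <- if (is.null(cell$priors)) uniform_priors(spec) else cell$priors
  rho_col <- spec$p + 1L
  est <- matrix(NA_real_, cell$reps, 4,
                dimnames = list(NULL, c("pml", "map", "med", "eap")))
  ints <- list(
    pml = matrix(NA_real_, cell$reps, 2),
    eap = matrix(NA_real_, cell$reps, 2)
  )
  fail <- 0L
  for (r in seq_len(cell$reps)) {
    x <- gen_cell_data(cell, spec, theta, r)
    mom <- if (cell$robust) huber_moments(x) else moments_from_data(x)
    ok <- tryCatch({
      fit <- suppressWarnings(fit_pml(mom, spec, priors))
      est[r, "pml"] <- fit$point[rho_col]
      if (!is.null(fit$se)) {
        ints$pml[r, ] <- fit$point[rho_col] + c(-1.96, 1.96) * fit$se[rho_col]
      }
      cfg <- cell$chain
      cfg$seed <- rep_seed(cell$base_seed, cell$cell_id + 10000L, r)
      ch <- run_chain(mom, spec, priors, cfg)
      pe <- chain_point_estimates(ch)
      est[r, "eap"] <- pe$eap[rho_col]
      est[r, "med"] <- pe$med[rho_col]
      est[r, "map"] <- pe$map[rho_col]
      ints$eap[r, ] <- pe$bci[, rho_col]
      TRUE
    }, error = function(err) FALSE)
    if (!ok) fail <- fail + 1L
  }
  finish_cell(cell, est, intervals = ints, failures = fail)
}

finish_cell <- function(cell, est, intervals, failures) {
  metrics <- cell_metrics(est, cell$rho, intervals)
  structure(list(cell = cell, estimates = est, intervals = intervals,
                 metrics = metrics, failures = failures),
            class = "cell_result")
}

# Aggregate bias / SD / RMSE / RMSE gain / coverage over the replication set.
cell_metrics <- function(est, truth, intervals = NULL, reference = "pml") {
  out <- do.call(rbind, lapply(colnames(est), function(m) {
    e <- est[, m]
    e <- e[!is.na(e)]
    bias <- mean(e) - truth
    sdv <- stats::sd(e)
    data.frame(estimator = m, bias = bias, sd = sdv,
               rmse = sqrt(bias^2 + stats::var(e)),
               coverage = NA_real_, n_covered = NA_integer_,
               stringsAsFactors = FALSE)
  }))
  if (!is.null(intervals)) {
    for (m in names(intervals)) {
      cv <- coverage_rate(intervals[[m]], truth)
      out$coverage[out$estimator == m] <- cv
      out$n_covered[out$estimator == m] <- attr(cv, "n_used")
    }
  }
  ref_rmse <- out$rmse[out$estimator == reference]
  out$rmse_gain <- if (length(ref_rmse) == 1 && is.finite(ref_rmse)) {
    100 * out$rmse / ref_rmse
  } else NA_real_
  out
}

#' @export
print.cell_result <- function(x, ...) {
  c_ <- x$cell
  cat(sprintf("Cell: rho = %.2f, n = %d, R = %d, engine = %s, skew/kurt = %g/%g\n",
              c_$rho, c_$n, c_$reps, c_$engine, c_$skew, c_$ex_kurt))
  if (x$failures > 0) cat("  failed replications:", x$failures, "\n")
  print(transform(x$metrics,
                  bias = round(bias, 3), sd = round(sd, 3),
                  rmse = round(rmse, 3), rmse_gain = round(rmse_gain, 0)))
  invisible(x)
}

#' Coverage rate of a set of 95% intervals
#'
#' @param intervals Matrix with one row per replication and columns
#'   (lower, upper); rows with missing endpoints are excluded and counted.
#' @param truth True parameter value.
#' @return Percentage of intervals containing the truth, with attributes
#'   `n_used`, `n_missing`, and `acceptable` (inside the 91-98% band).
#' @export
coverage_rate <- function(intervals, truth) {
  intervals <- as.matrix(intervals)
  ok <- stats::complete.cases(intervals)
  used <- intervals[ok, , drop = FALSE]
  if (nrow(used) == 0) {
    out <- NA_real_
  } else {
    out <- 100 * mean(used[, 1] <= truth & truth <= used[, 2])
  }
  attr(out, "n_used") <- nrow(used)
  attr(out, "n_missing") <- sum(!ok)
  attr(out, "acceptable") <- !is.na(out) && out >= 91 && out <= 98
  out
}

#' Estimation-problem rates for unconstrained vs constrained ML
#'
#' Runs `reps` replications of a cell, fitting both unconstrained ML (single
#' standard start, optimizer defaults) and constrained ML, and tabulates the
#' percentage of replications that converged, converged with an admissible
#' correlation estimate (|rho| <= 1), hit the constrained boundary, and where
#' the two estimators numerically agree (|difference in rho| < 1e-4 among
#' replications with a converged unconstrained solution).
#'
#' Boundary solutions are counted on the correlation (|rho| at 1 - epsilon),
#' the quantity whose truncation the constrained fit prevents.
#'
#' @param rho,n,lambda True parameters and sample size.
#' @param reps Number of replications.
#' @param base_seed,cell_id Seeding as in [design_cell()].
#' @return List with `rates` (percentages: `pct_converged`,
#'   `pct_converged_admissible`, `pct_boundary`, `pct_ml_equals_cml`) and the
#'   per-replication data frame `reps`.
#' @export
ml_problem_rates <- function(rho, n, lambda = 0.5, reps = 200,
                             base_seed = 1, cell_id = 1L) {
  spec <- cfa_model_spec()
  theta <- cfa_parameters(lambda, rho, spec = spec)
  rho_col <- spec$p + 1L
  rows <- vector("list", reps)
  for (r in seq_len(reps)) {
    x <- gen_normal(theta, spec, n, seed = rep_seed(base_seed, cell_id, r))
    mom <- moments_from_data(x)
    fu <- tryCatch(suppressWarnings(fit_ml_unconstrained(mom, spec, se = FALSE)),
                   error = function(e) NULL)
    fc <- suppressWarnings(fit_ml_constrained(mom, spec, se = FALSE))
    conv <- !is.null(fu) && fu$status == "converged"
    rows[[r]] <- data.frame(
      converged = conv,
      admissible = conv && fu$admissible,
      rho_ml = if (!is.null(fu)) fu$unstd$rho else NA_real_,
      rho_cml = fc$point[rho_col],
      boundary = abs(fc$point[rho_col]) >= 1 - spec$epsilon - 1e-6
    )
  }
  df <- do.call(rbind, rows)
  agree <- df$converged & !is.na(df$rho_ml) &
    abs(df$rho_ml - df$rho_cml) < 1e-4
  list(rates = c(pct_converged = 100 * mean(df$converged),
                 pct_converged_admissible = 100 * mean(df$admissible),
                 pct_boundary = 100 * mean(df$boundary),
                 pct_ml_equals_cml = 100 * mean(agree)),
       reps = df)
}

#' Long-format summary of one or more cell results
#'
#' Stacks cell metrics into a stable long schema (one row per estimator and
#' metric) with the cell design attached, suitable for writing to delimited
#' text and recomputing table layouts.
#'
#' @param results A `"cell_result"` or list of them.
#' @return Data frame with columns `rho`, `n`, `reps`, `engine`, `skew`,
#'   `ex_kurt`, `mu_rho`, `nu_rho`, `mu_lambda`, `nu_lambda`, `estimator`,
#'   `metric`, `value`, ordered deterministically.
#' @export
summarize_tables <- function(results) {
  if (inherits(results, "cell_result")) results <- list(results)
  out <- do.call(rbind, lapply(results, function(res) {
    cell <- res$cell
    pr <- cell$priors
    long <- stats::reshape(
      res$metrics[, c("estimator", "bias", "sd", "rmse", "rmse_gain", "coverage")],
      direction = "long",
      varying = c("bias", "sd", "rmse", "rmse_gain", "coverage"),
      v.names = "value", timevar = "metric",
      times = c("bias", "sd", "rmse", "rmse_gain", "coverage"))
    data.frame(rho = cell$rho, n = cell$n, reps = cell$reps,
               engine = cell$engine, skew = cell$skew, ex_kurt = cell$ex_kurt,
               mu_rho = if (is.null(pr)) 0 else pr$rho$mu,
               nu_rho = if (is.null(pr)) 0 else pr$rho$nu,
               mu_lambda = if (is.null(pr)) 0.5 else pr$lambda$mu,
               nu_lambda = if (is.null(pr)) 0 else pr$lambda$nu,
               estimator = long$estimator, metric = long$metric,
               value = long$value, row.names = NULL)
  }))
  out[order(out$rho, out$n, out$estimator, out$metric), ]
}
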