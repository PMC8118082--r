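---
title: "Estimating small-sample CFA models: penalized likelihood, grid posteriors, and adaptive MCMC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating small-sample CFA models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smallcfa)
```

## The problem

Confirmatory factor analysis (CFA) corrects correlations between psychological
constructs for measurement error: each construct (latent factor) is measured
by several error-prone indicators, and the correlation of interest is the one
between the factors, not between fallible sum scores. Maximum likelihood (ML)
handles this well at large sample sizes but becomes fragile when `n` is small
relative to the model: optimizers fail to converge, and estimated correlations
land outside `[-1, 1]`. `smallcfa` implements a family of estimators that
stabilize this problem for the two-factor, six-indicator model and evaluates
them from a frequentist point of view.

## Model and parameterization

The model is `x = Lambda eta + eps` with two unit-variance factors, simple
structure (each indicator loads on one factor), and saturated means. Rather
than unstandardized loadings and residual variances, the package parameterizes
by *bounded* quantities:

* standardized loadings `lambda_j` in `(0, 1)`,
* the latent correlation `rho` in `(-1, 1)`,
* indicator standard deviations `sigma_j > 0`.

The implied covariance is `Sigma[i, j] = sigma_i sigma_j lambda_i lambda_j
phi[m(i), m(j)]` with unit diagonal scaled by `sigma_j^2`. The two
parameterizations are equivalent (`sigma_j^2 = lambda*_j^2 + omega_jj`,
`lambda_j = lambda*_j / sigma_j`); the bounded one makes the admissible region
a box, which is what lets constrained optimization and bounded priors work.
Bounds are kept a small offset `epsilon = 0.001` (configurable) inside the
natural range so that likelihood derivatives stay finite at constrained
optima.

The marginal log-likelihood, with the latent factors integrated out, depends
on the data only through the sample covariance `S` (divisor `n`) and the
sample size:

$$ l(\theta) = -\tfrac{n}{2}\left[p \log 2\pi + \log|\Sigma(\theta)| +
   \mathrm{tr}(\Sigma(\theta)^{-1} S)\right]. $$

Evaluation uses a Cholesky factorization; a non-positive-definite
`Sigma(theta)` returns `-Inf` so optimizers and samplers reject such points
without special-casing.

A practical aid for prior elicitation is the tau-congeneric reliability map:
with `I` items of common loading `lambda`, the sum-score reliability is
`Rel_I = lambda^2 / (lambda^2 + (1 - lambda^2)/I)` ([reliability_sum()],
inverted by [loading_from_reliability()]). Researchers usually have a feel for
scale reliability, and this translates it into a loading prior guess.

## Priors

Bounded parameters get four-parameter beta priors `Beta4(a, b, l, u)`, i.e. a
beta distribution stretched onto `[l, u]`. The elicitation parameterization is
a prior guess `mu` and a prior sample size `nu` with `a = (nu + 2)(mu - l)/(u
- l)`, `b = (nu + 2)(u - mu)/(u - l)`; `nu = 0` with `mu` at the interval
midpoint is the uniform prior, and larger `nu` concentrates mass around `mu`
(on `[0, 1]` the variance is `mu (1 - mu)/(nu + 3)`). Loadings live on
`[epsilon, 1 - epsilon]`, the correlation on `[-1 + epsilon, 1 - epsilon]`.
Indicator SDs get an improper constant prior, flat on the `sigma` scale (not
`log sigma`); this is a documented choice — the SD prior never enters reported
standard errors, so the choice is inert for the reported uncertainty.

## Estimators

Four deterministic fits share one bounded quasi-Newton backbone (`nlminb`,
five dispersed starts: loadings 0.5 with `rho` in {-0.5, 0, 0.5}, and loadings
{0.25, 0.75} with `rho = 0`; SD starts from `diag(S)`):

* `fit_ml_unconstrained()` — the unstandardized parameterization with no
  bounds and a single standard start, mirroring default SEM software. It is
  *supposed* to misbehave at small `n`; non-convergence and inadmissible
  `|rho| > 1` are flagged, never repaired.
* `fit_ml_constrained()` — the bounded parameterization under box
  constraints.
* `fit_pml()` — penalized ML: maximizes `l(theta) + log pi(theta)`, the mode
  of the joint posterior. With uniform priors this *is* constrained ML.
* `fit_uls()` — unweighted least squares on `S - Sigma(theta)`.

Standard errors come from the observed information of the likelihood only
(finite-difference Hessian, symmetrized); the prior is deliberately excluded
— it stabilizes the point estimate but including it in the curvature would
understate frequentist uncertainty. Estimates at a box bound are pulled
inward by `epsilon` before differentiation. Confidence intervals are Wald,
`point ± 1.96 se`.

One numerical subtlety: the penalty is evaluated relative to its value at a
fixed interior reference point. Additive prior constants then cancel exactly,
so with uniform priors the penalized objective is bit-identical to the
likelihood and the identity `PML(uniform) = CML` holds to machine precision
instead of optimizer tolerance (relative-tolerance stopping rules are
sensitive to additive shifts on flat small-`n` likelihoods).

## Bayesian point estimates: joint mode vs marginal summaries

The mode of the joint posterior (PML) is not the same object as the mean
(EAP), median (Med), or mode (MAP) of a parameter's *marginal* posterior. For
skewed small-sample posteriors they can differ a lot, and the differences are
exactly what the package's simulation harness measures. Two engines compute
the marginal summaries:

**Grid integration** (`build_grid()`, `marginal_rho()`,
`marginal_point_estimates()`, `joint_mode()`). For the equal-loading model
with fixed SDs only `(rho, lambda)` are free, so the posterior is evaluated
exactly on a regular grid of cell midpoints and normalized by the rectangle
rule. The default step is 0.002 on both axes; halving it moves the EAP by
less than 1e-3 (checked in the tests), which justifies the default. The
implied covariance of this model is diagonal-plus-rank-2, so the determinant
lemma and the Woodbury identity reduce each grid cell to 2x2 algebra; the
data enter only through `tr(S)` and three block sums of `S`. This makes the
grid engine fast enough to run a thousand replications in under a minute, and
it is cross-checked against the generic likelihood in the tests. The median
interpolates linearly inside the cell where the cumulative sum crosses 0.5;
modes are refined by a local three-point parabola; ties break to the
lowest-index cell.

**Adaptive Metropolis-within-Gibbs** (`run_chain()`). For the full
13-parameter model the marginal summaries need MCMC. Each iteration sweeps
the parameters in fixed order; each coordinate gets a symmetric normal
proposal accepted by the Metropolis rule on likelihood times that
coordinate's prior. Proposals outside the prior support (including
non-positive SDs) are rejected and the current value retained, which keeps
the stationary distribution the truncated posterior. During burn-in, each
proposal SD is adapted at the end of every 50-iteration batch: inflated by `2
- (1 - r*)/(1 - r)` when the batch acceptance rate `r*` exceeds `r + delta`,
divided by `2 - r*/r` when it falls below `r - delta`, otherwise left alone
(`r = 0.45`, `delta = 0.10`). Adaptation stops at the end of burn-in.
Defaults are 5000 iterations with 2500 burn-in. Initial proposal SDs (0.2 for
loadings and correlation, half the indicator SD for `sigma`) are weakly
influential because of the adaptation. The average realized acceptance rate
sits near 0.45; individual parameters scatter roughly +/-0.1 around it
because a 50-iteration batch estimates its acceptance rate with a standard
error of about 0.07 — single-batch adaptation cannot pin every coordinate
into a tighter band, and the package does not pretend otherwise.

Chain summaries: EAP is the draw mean, Med the draw median, MAP the mode of a
Gaussian kernel density estimate (Silverman bandwidth, 512-point grid), and
`pml_mcmc` the retained draw maximizing the unnormalized log posterior.
Credible intervals are central 95% percentile intervals. `mcmc_diagnostics()`
provides the potential scale reduction factor (split-chain variant when only
one chain exists) and an effective sample size from the truncated
autocorrelation sum. The sampler core is C++ (Rcpp/RcppArmadillo) but uses
R's RNG, so `set.seed()` gives bit-identical chains; the pure-R likelihood is
kept as an independent implementation and the two are compared in the tests.

## Synthetic data

`gen_normal()` draws multivariate normal indicators with covariance
`Sigma(theta)`. `gen_nonnormal()` produces indicators with prescribed
marginal skewness and excess kurtosis while preserving the covariance
structure: each margin is a third-order polynomial `a + bZ + cZ^2 + dZ^3` of
a standard normal, with coefficients solved by damped Newton iteration from
the start `(b, c, d) = (1, 0, 0)` (restarts on failure), and the correlations
of the underlying normals are pre-adjusted pair by pair through the cubic
correlation identity so that the *transformed* variables hit the target
correlations. The necessary feasibility condition `ex_kurt >= skew^2 - 2` is
enforced with an explicit error. With targets (0, 0) the transform is the
identity and the output is draw-for-draw identical to `gen_normal()` at the
same seed. One (skew, kurtosis) pair applies to all six indicators by
default, with per-indicator overrides available.

What the generator emulates — and what it does not: it produces linearly
related indicators with exact second moments and controlled third/fourth
marginal moments. Real questionnaire data additionally feature ordinal
response scales, missingness, cross-loadings, and dependence structures
beyond linear correlation. Passing tests therefore demonstrate correctness of
the estimators under the stated sampling models, not robustness to everything
real data can do.

## The simulation harness

`run_cell()` runs one design cell (true `rho`, `n`, loading 0.5, prior
configuration, distribution shape) for `R` replications: generate data,
reduce to moments (optionally Huber-type robust moments), estimate, and
aggregate bias, empirical SD, `RMSE = sqrt(bias^2 + var)` over the same
replication set, RMSE as a percentage of the flat-prior PML reference (100 =
reference), and coverage of the 95% intervals (Wald for PML, percentile for
the chain), flagged against the 91–98% acceptability band. Per-replication
seeds are an integer hash of (base seed, cell id, replication), so any cell
or single replication can be rerun independently. `ml_problem_rates()`
tabulates the estimation-problem taxonomy: percent converged, percent
converged-and-admissible, percent of constrained solutions with the
correlation at its bound, and percent of replications where unconstrained and
constrained ML agree to 1e-4. Boundary counting is on the correlation — the
quantity whose truncation the bounds prevent; loadings also touch their
bounds on flat likelihoods, but that is not the estimation problem the
taxonomy tracks.

Problem sizes used by the packaged checks: the illustrative grid cells run
R = 1000 replications (the grid engine makes this cheap); the MCMC cell runs
R = 250 with 5000-iteration chains, which estimates an RMSE ratio to within a
few percentage points; the chain-versus-grid comparison uses a single
60 000-iteration chain. These sizes keep every check on a single CPU within
minutes while leaving Monte-Carlo error well inside the tolerances asserted.

## Behavior worth knowing about

* At `n = 30` with a true correlation of 0.70 and saturated moments, the
  marginal posterior of `rho` under flat priors is left-skewed: the joint
  mode sits at 0.700 while the marginal mean is pulled to about 0.57
  (shrinkage). With `n = 100` the spread narrows. The EAP trades this bias
  for a smaller sampling variance, and in small-`n`, small-to-moderate `rho`
  cells its RMSE beats the PML's; with large true correlations the bias
  dominates and the advantage reverses.
* The KDE-based MAP from the chain is bandwidth-dependent. With the
  Silverman default used here it is smoother (hence less variable) than a
  raw marginal argmax; its RMSE consequently lands *below* the PML's in the
  small-`n` cells, while sharper bandwidth choices push it above. The
  package treats the bandwidth as an explicit, documented choice rather than
  a tuned quantity.
* The improper flat SD prior and the likelihood-only standard errors are
  choices with alternatives (flat on `log sigma`; prior-inclusive curvature).
  Both alternatives are easy to add behind the same interfaces; the shipped
  defaults are the ones whose frequentist behavior the harness measures.
* The Huber-type moments use weights `min(1, k/d)` on Mahalanobis distances
  with `k = sqrt(qchisq(0.95, p))`, weights on means and squared weights on
  covariances with an empirical consistency rescaling, so clean normal data
  reproduce the classical moments. Robust-moment literature contains several
  variants; this one is deliberately swappable.

## Limitations

Only the two-factor, simple-structure model is exercised end to end; the
data structures generalize (a full factor correlation matrix with a
determinant check) but grids beyond two free parameters are intentionally out
of scope. Ordinal indicators, cross-loadings, mean structures, and
fit-index/likelihood-ratio machinery are not implemented. Coverage of
chain-based intervals inherits the bias of the point estimates: a strongly
informative, misplaced prior yields intervals that undercover even though
the interval construction itself is sound.
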