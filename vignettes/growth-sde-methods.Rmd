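---
title: "Drift-and-diffusion models for childhood growth: methods"
author: "growthsde"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drift-and-diffusion models for childhood growth: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(growthsde)
```

## The model family

A child's weight-for-length z-score (ZWfL) is modelled as a continuous-time
stochastic process

$$dX_t = \bigl(p(t) + a_1 X_t\bigr)\,dt + s\,dW_t,
\qquad p(t) = a_2 + a_3 t + a_4 t^2 + a_5 t^3,$$

with age $t$ in months. The *drift* $p(t) + a_1 X_t$ is the slow-moving
trend in growth velocity — developmental physiology, nutrition — and the
*diffusion* $s\,dW_t$ is the continual stream of short-term perturbations
(illness, infection, food insecurity) that makes real trajectories so
irregular. Two special cases anchor the family:

* the **Ornstein–Uhlenbeck (OU) process** $dX = \alpha(\beta - X)dt +
  \sigma dW$, obtained with `drift_order = 0` and $a_1 = -\alpha$,
  $a_2 = \alpha\beta$: trajectories revert at speed $\alpha$ towards a
  long-term level $\beta$;
* the **cubic-drift model** (`drift_order = 3` with mean reversion), whose
  age polynomial lets the attracting level itself move over the first two
  years.

Nonlinear-in-$X$ drifts and state-dependent diffusions are deliberately out
of scope: they have no closed-form transition density and would need
numerical likelihood machinery.

## Slice densities

Because the drift is linear in $X$ and the diffusion constant, the
transition ("slice") density between any two ages is Gaussian:

$$X_{t_1} \mid X_{t_0} = x_0 \;\sim\; N\!\bigl(m(t_1),\, v(t_1)\bigr),
\qquad
m = e^{a_1\Delta}x_0 + \int_{t_0}^{t_1} e^{a_1(t_1-u)}\,p(u)\,du,
\quad
v = s^2\,\frac{e^{2a_1\Delta}-1}{2a_1},$$

with $\Delta = t_1 - t_0$. Rather than evaluating the expanded
exponential-polynomial expression (which cancels catastrophically as
$a_1 \to 0$), the implementation expands $p$ around $t_0$ and writes both
moments through the exponential-integrator functions
$\varphi_k(z) = \sum_{n\ge 0} z^n/(n+k)!$:

$$m = e^{z}x_0 + \sum_{j=0}^{3} c_j\, j!\, \Delta^{j+1} \varphi_{j+1}(z),
\qquad v = s^2\,\Delta\,\varphi_1(2z), \qquad z = a_1\Delta,$$

where $c_j = p^{(j)}(t_0)/j!$. The $\varphi_k$ are computed by a Taylor
series for $|z| < 0.9$ and the stable upward recurrence
$\varphi_{k+1}(z) = (\varphi_k(z) - 1/k!)/z$ otherwise, so the same code
path covers mean-reverting, expanding ($a_1 > 0$) and driftless
($a_1 = 0$) models; the test suite checks continuity across $a_1 = 0$ at
$10^{-6}$ and agreement with the expanded closed forms and with
Euler–Maruyama simulation. `euler_maruyama()` exists precisely as that
brute-force cross-check; `sample_transition()` is the exact simulator used
everywhere else.

## Likelihood

For a child observed at ages $t_0 < \dots < t_{N-1}$ the negative
log-likelihood is the sum of negative log slice densities over consecutive
transitions. The first observation is treated as a constant and
contributes no term — the standard convention for maximum likelihood in
SDEs and time series. (An alternative would be to start the process from
its stationary density; `trajectory_negloglik()` deliberately implements
the conditioning convention only, as the stationary density does not exist
for all family members.) Irregular gaps and missed visits need no
imputation: each transition simply spans the observed age difference,
which is the core practical advantage of the transition formulation over
curve fitting.

Fitting (`fit_mle()`) is multi-start bounded quasi-Newton on transformed
parameters — $\log s$, and $\log\alpha$ in the OU parameterisation, so
positivity is structural while $a_1$ remains free in sign in the natural
parameterisation. Defaults: 5 restarts from jittered moment-matching
starting values with fixed restart seeds (fits never consume the caller's
RNG stream), `nlminb` with a relative tolerance of $10^{-10}$, standard
errors from the finite-difference observed information, delta method back
to the natural scale.

Site enters the drift parameters additively and the diffusion on the log
scale. The log scale for $s$ is a convention choice (the alternative — an
additive offset on $s$ itself — can produce invalid negative diffusions
during optimisation); it is flagged as a convention, not an empirical
claim.

## Mixed effects

Child-level random effects $b_i \sim N(0, \Sigma_b)$ act additively on
selected transformed parameters (so effects on $s$, or on $\alpha$ in the
OU parameterisation, live on the log scale). The marginal likelihood
$\prod_i \int L_i(\theta, b_i)\,\phi(b_i; 0, \Sigma_b)\,db_i$ is computed
by adaptive Gauss–Hermite quadrature: per child, the integrand's mode and
curvature are found (a vectorised damped Newton across all children in the
one-dimensional case) and 5 curvature-rescaled Hermite nodes per dimension
are combined by log-sum-exp. Beyond two random-effect dimensions the
Laplace approximation (the 1-node special case) is used. The test suite
checks that 5-node and 21-node quadrature agree to $10^{-3}$ on fitted
models. $\Sigma_b$ is parameterised through its Cholesky factor with log
diagonal, so every optimiser iterate is a valid covariance and the
"estimate not positive semi-definite" failure mode cannot occur; both
diagonal and unstructured factors are supported, neither privileged.

Starting values matter here: a pooled fixed-effects fit confounds
between-child spread with slow mean reversion (a cohort of children each
reverting quickly to *different* levels looks, pooled, like one process
reverting slowly to the average). `fit_mixed_sde()` therefore always
tries two starts — the fixed-effects MLE, and a within-child
moment-matching start in which per-child trajectory means estimate the
random-level spread and child-centred regression estimates the reversion
speed — and keeps the better optimum.

Empirical-Bayes effects $\hat b_i$ are the per-child posterior modes at
the fitted parameters; they shrink towards zero as a child's data are
truncated, which the tests verify on paired children.

## Baselines, information criteria and model search

Two fixed-effect baselines mirror the classical comparisons: the naive
linear transition model $X_1 \mid X_0 \sim N(X_0 + b\Delta, \sigma^2)$ and
the global linear regression $X(t) \sim N(a_0 + a_1 t, \sigma^2)$. The LMM
baseline (`fit_lmm()`) is a polynomial-in-age mixed model with optional
site interactions, unstructured (or diagonal) random effects on the age
terms and AR(1) or independent within-child errors, fitted by ML through
`nlme`; its AIC/BIC are directly comparable with the SDE fits on the same
cohort.

Conventions, stated so comparisons are internally consistent: AIC
$= 2k - 2\log L$ and BIC $= k\log n - 2\log L$ with $k$ counting fixed
effects plus variance/covariance parameters and $n$ the total number of
observation rows (not transitions). `model_search()` enumerates polynomial
orders (cubic at most for the SDE drift, quartic for the LMM) and
candidate random-effect structures, and iteratively removes the weakest
fixed term while its Wald p-value (observed-information z test, matching
the default of the usual nonlinear mixed-model software) exceeds 0.1; a
term at or below the cut is never removed. All candidate fits are returned
ranked by AIC with BIC alongside; failed candidates are recorded, never
fatal.

## Prediction

`predict_field()` implements grid-based forecasting with likelihood
"locality". Every fitted child contributes one parameter set (fixed
effects plus its empirical-Bayes effects). For a grid point $(t, x)$, each
child is scored by the slice-density value of that point for a process
started at the child's own first observation — a single-slice reading of
"how likely is this child to pass here". (A stricter reading — the
likelihood of a whole path visiting the point — is noted as an
alternative; the single-slice form is simple, fast and monotone in the
same distance.) A predicted path then advances in small age steps
(default 0.1 months, chosen so that halving it moves 24-month predictions
by well under 0.05 z): at each step the currently most likely parameter
set is re-selected — so the chosen child may switch along a path — and the
state moves to the slice-density *mean* of the chosen set over the step.
The mean, rather than a random draw, gives the "most likely" path and a
deterministic field. Ten sensitivity paths per start repeat the walk
within 10 seeded random groups of children. Degenerate corner: at a
child's own anchor the slice density at $\Delta t = 0$ is a point mass,
ranked with a $+\infty$ sentinel and deterministic tie-break by child
order; children whose first observation is later than the current age are
excluded (score 0), and a path truncates with a warning if no candidate
remains.

On cohorts containing well-separated growth regimes this machinery
reproduces the qualitative "streams" phenomenon: predictions from a grid
of starting points converge onto a small number of bands ending near the
regimes' stationary means, and the fold paths track the main path closely
— the canalisation behaviour the method was designed to expose.

## The synthetic-cohort generator

No individual-level data ship with the package; `simulate_cohort()`
stands in for the kind of two-site birth-cohort data the models target.
It emulates:

* a target schedule of monthly visits over ages 0–24 months (25 visits);
* visit-age jitter from a truncated normal with sd 5 days, hard-capped at
  the ±14-day visit window (converted to months by 30.4375 days/month);
* independent per-visit Bernoulli missingness (default probability 0.03,
  under which `pbinom(1, 24, 0.03)` ≈ 84% of children keep at least 24 of
  25 visits, matching the published completeness levels of the motivating
  cohorts); the first visit is never dropped, since a trajectory needs an
  anchor;
* per-site initial values $X_0 \sim N(0, 1)$ by default — the transition
  models condition on $X_0$ and never model it, so the generator must
  supply one; mean 0 and sd 1 are a realistic choice for birth z-scores
  against a growth standard;
* child-level Gaussian random effects drawn once per child and held fixed,
  and additive site offsets in drift and (log-)diffusion.

It does **not** emulate informative missingness (the true dropout
mechanism behind the published completeness figures is unknown; Bernoulli
is a documented stand-in), measurement error (the motivating data were
collected with minimal measurement error), or the WHO z-score construction
from raw weight and length — cohorts enter the package already
standardised. Passing tests therefore demonstrate correctness of the
estimators under the stated generating mechanisms, not robustness to
informative dropout or measurement noise.

## Problem sizes and numerical tolerances used in the tests

The test suite exercises the estimators at the scales the methods are
meant for while staying quick to run: fixed-effect recovery at 20
replicates of 200 children × 25 scheduled visits; mixed-effects recovery
at 100 children × 25 visits; model-comparison direction at 20 replicates
(100 children for fixed effects, 60 for mixed); Monte-Carlo checks with
$10^5$ Euler–Maruyama paths at step $10^{-3}$ against 4 Monte-Carlo
standard errors; algebraic identities (OU reduction, Chapman–Kolmogorov,
likelihood oracle) at $10^{-12}$–$10^{-10}$. Statistical checks use "within
3 reported standard errors" as the recovery criterion, with the binomial
allowance (at least 17 of 20 replicates) where replicated.

## Known limitations

* Standard errors are observed-information Wald throughout; no profile or
  bootstrap intervals.
* The marginal likelihood beyond two random-effect dimensions is Laplace
  only; quadrature accuracy is verified in one dimension.
* The prediction method is deliberately simple — no formal predictive
  intervals; the 10-fold spread is an indication of robustness, not a
  confidence band.
* Model search is greedy (one term removed at a time) and inherits the
  usual caveats of stepwise selection.

## A minimal end-to-end run

```{r example, eval = FALSE}
model <- ou_model(alpha = 1.2, beta = -0.8, sigma = 0.6)
design <- cohort_design(n_children_per_site = 100, sites = "A", seed = 1)
cohort <- simulate_cohort(model, design)

fit <- fit_mle(ou_model(1, 0, 1), cohort, parameterization = "ou")
fit

mixed <- fit_mixed_sde(ou_model(1, 0, 1), cohort, re_names = "beta",
                       parameterization = "ou")
grid <- prediction_grid(ages = c(1, 6), values = c(-2, 0, 1), step = 0.1)
field <- predict_field(mixed, cohort, grid, site = "A", seed = 1)
export_field(field, "field.csv")
```
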