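---
title: "Residual confounding, measurement reliability, and false power"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Residual confounding, measurement reliability, and false power}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(falsepower)
```

## The problem

An analyst wants to test whether an exposure X (say, energy intake) predicts
an outcome Y (say, blood pressure) after adjusting for a confounder Z (say,
sodium intake). The confounder is not observed; only an error-prone
measurement Z' is, and often the exposure too is observed only through an
error-prone instrument X'. Adjusting for Z' instead of Z removes only part
of the confounding. The part that leaks through — *residual confounding* —
shows up as a nonzero population partial correlation between the observed
exposure and Y given Z', even though X has no direct effect on Y at all.
A standard significance test of the adjusted association then rejects more
often than its nominal level; we call that excess rejection probability
**false power**. This package quantifies exactly how false power depends on
the measurement reliabilities, and under what circumstances the dependence
is monotone.

## The models

Everything is built on two standardized-normal path models under the
classical true-score conception of measurement error (observed = loading
times true score + independent zero-mean normal error).

**Model 1** (confounder mismeasured, exposure exact):

$$Y = \beta Z + \epsilon_y, \qquad X = \gamma Z + \epsilon_x, \qquad
  Z' = \alpha Z + e, \qquad Z \sim N(0, 1).$$

**Model 2** additionally passes the exposure through an instrument:
$X' = \alpha_x X + e_x$, $Z' = \alpha_z Z + e_z$.

All error terms are mutually independent and independent of Z, and their
variances are fixed so that every manifest variable has variance 1
(`error_variances()`); the models are then fully described by their
standardized loadings. The *reliability* of an instrument is the squared
loading ($\alpha^2$), the fraction of observed variance carried by the true
score. Negative loadings are allowed throughout — reliability is always the
square — and the closed forms below depend on the loadings only through
even powers, which the test suite checks by randomized sign flips.

Note that there is deliberately **no direct X→Y path**: the models encode
the null hypothesis of the adjusted test, so every rejection is a type I
error. The same algebra covers three superficially different questions —
testing an association adjusted for a confounder, testing a direct effect
beyond a mediator, and testing incremental predictive validity — because
all three reduce to the same partial correlation on the same correlation
matrix; reversing or undirecting the Z–X arrow changes the causal story but
not a single number.

## From path model to false power

Path tracing gives the implied correlations among the observed variables
(`implied_corr()`); e.g. for Model 2, $\rho_{X'Z'} = \alpha_x\gamma\alpha_z$,
$\rho_{Z'Y} = \beta\alpha_z$, $\rho_{X'Y} = \beta\gamma\alpha_x$. The
squared partial correlation of the exposure and outcome given the observed
confounder is assembled from the full- and reduced-model $R^2$:

$$R^2_{Y,X.Z'} = \frac{R^2_{Y.X,Z'} - R^2_{Y.Z'}}{1 - R^2_{Y.Z'}}.$$

Substituting the path products and simplifying yields compact closed forms:

* Model 1: $\dfrac{\beta^2\gamma^2(1-\alpha^2)^2}
  {(1-\gamma^2\alpha^2)(1-\alpha^2\beta^2)}$ — strictly decreasing in
  $\alpha$ on $(0,1)$, from $(\gamma\beta)^2$ at $\alpha = 0$ down to 0 at
  $\alpha = 1$. Improving the confounder instrument always helps.
* Model 2: $\dfrac{\beta^2\gamma^2\alpha_x^2(1-\alpha_z^2)^2}
  {(1-\gamma^2\alpha_x^2\alpha_z^2)(1-\alpha_z^2\beta^2)}$ —
  non-increasing in $\alpha_z$ at fixed $\alpha_x$, and increasing in
  $|\alpha_x|$: a noisier exposure instrument *attenuates* the spurious
  association just as it would a real one.

The superficially alarming non-monotonicity arises only when the two
reliabilities are **tied**, $\alpha_x = \alpha_z = \alpha$
(`partial_r2_model2_constrained()`): the curve then vanishes at both
endpoints and peaks at an interior $\alpha^*$, the root of the polynomial
$-1 + 3\alpha^2 + \alpha^6(2\beta^2 - 1)\gamma^2 - \alpha^4(2\beta^2 +
\gamma^2)$ (`critical_point()`). Two opposing forces are moving at
different rates: raising $\alpha$ strengthens the adjustment (pushing bias
down) but simultaneously strengthens the exposure signal that carries the
bias (pushing measured bias up). The package makes the decoupling explicit
with the link $\alpha_x = \omega\alpha_z + a_0$ (`partial_r2_omega()`);
with $\beta = \gamma = 1$, $\omega = -1$ the curve collapses to
$\alpha_z^2/(1+\alpha_z^2)$, monotone with limit 1/2.

Both derivative formulas (`d_partial_r2_model1()`,
`d_partial_r2_model2_constrained()`) were re-derived by hand from the
closed forms and are verified against central-difference numerical
differentiation over randomized parameters in the test suite.

Finally, `false_power()` converts a population squared partial correlation
$\rho_p^2$ into a rejection probability: the 1-df partial F statistic of
the OLS fit of Y on (exposure, confounder) is noncentral
$F(1, n-3, \lambda)$ with $\lambda = (n-3)\rho_p^2/(1-\rho_p^2)$, and false
power is the mass above the central critical value. The noncentrality
convention is not a free choice left to taste: it is pinned down
empirically by the requirement that analytic false power match Monte Carlo
rejection rates within binomial error, which the acceptance tests check at
20,000 replicates across a grid of reliabilities. False power is increasing
in both $\rho_p^2$ and n — large cohorts are the *most* exposed to this
bias, not the least.

### Two F conventions

`f_from_r2()` implements the ratio
$[(R^2_{full} - R^2_{red})/(1 - R^2_{red})]\,(N-3)$, whose left factor is
exactly the squared partial correlation. The textbook hierarchical F
divides instead by $1 - R^2_{full}$. Both are monotone in the partial
correlation at fixed n, so every shape conclusion is convention-free; the
simulator uses the standard OLS partial t by default and offers the ratio
form as `rejection_rate(statistic = "r2_ratio")` for comparison (it is
slightly conservative).

## The simulation engine

`draw_sample()` generates data exactly by the path equations — latent Z
first, then each manifest variable as loading × parent + independent normal
error with the standardizing variance. This is a faithful emulation of the
model, which also means it inherits the model's idealizations: normality,
homoscedasticity, independent errors, linearity, a single confounder, and
exactly classical (nondifferential, additive) measurement error. Passing
tests therefore validate the algebra and the testing machinery, not the
behaviour of real dietary data, which exhibit systematic and differential
misreporting the classical model cannot represent.

`fit_partial_test()` runs the standard OLS regression `y ~ x + z` via
`stats::lm` and reports the two-sided t test of the exposure coefficient
and the sample squared partial correlation $t^2/(t^2 + n - 3)$.
`rejection_rate()` vectorises the identical test across replicates using
the algebraic identity between the OLS t and the sample partial correlation
$r_p = (r_{xy} - r_{xz}r_{zy})/\sqrt{(1-r_{xz}^2)(1-r_{zy}^2)}$; the two
routes are cross-checked against each other in the tests. Replicates come
from a single RNG stream seeded once per call and processed in fixed-size
chunks; since the package runs no parallel code, this is exactly
reproducible for a given seed, and it keeps 20,000-replicate runs to a few
seconds. Default replicate count is 10,000 (binomial SE at the 5% level
≈ 0.002); verification runs in the test suite use 20,000 where a claim is
checked to within three binomial standard errors, and smaller counts where
the claim under test has a large margin. Convergence checks use sample
sizes 500, 5,000 and 200,000.

## Numerical choices

* **Cancellation-free closed forms.** Factors like $(1-\alpha^2)^2$ are
  evaluated as $((1-\alpha)(1+\alpha))^2$, and denominator factors as sums
  of nonnegative terms (e.g. $1-(\alpha_z\beta)^2 =
  (1-\alpha_z^2) + \alpha_z^2(1-\beta)(1+\beta)$). Near $\alpha = 1$ the
  naive arrangements lose up to ten significant digits (the printed reduced
  form contains $1-\alpha_z^2(2-\alpha_z^2)$, which is $(1-\alpha_z^2)^2$
  in disguise); the stable arrangements agree with the exact identity
  $\alpha_z^2/(1+\alpha_z^2)$ to machine precision along the whole grid.
* **Domains.** Loadings live in the closed interval $[-1, 1]$; boundary
  values are generatively fine (zero error variance) and the closed forms
  are continuous there. Vanishing denominators (e.g. $|\alpha\beta| \to 1$)
  raise a distinct singularity error rather than returning clipped values.
  Limits are probed by explicit evaluation at $1 - \varepsilon$ (default
  $\varepsilon = 10^{-8}$ in the tests, $10^{-6}$ as the grid endpoint).
* **Critical points** are found by bisection to $10^{-12}$ on the bracketed
  polynomial factor of the derivative, not on the derivative itself: the
  prefactor $2\alpha(\alpha^2-1)\beta^2\gamma^2$ vanishes at both interval
  endpoints and would hand spurious roots to a generic root finder.
* **Shape classification** (`classify_monotonicity()`) uses a 512-point
  grid on $[0, 1-10^{-6}]$ with differences below $10^{-10}$ treated as
  flat. More than one direction change is an error by design: no curve in
  this family can do that, so seeing it means a formula bug.

## The design module

The design question — given a budget, should the next dollar buy subjects,
a better exposure instrument, or a better confounder instrument? — is
posed in the literature as an open framework. This module is one deliberate
instantiation of it, and its functional forms are package decisions, not
established results:

* **Cost of reliability** uses the odds transform $r/(1-r)$ per instrument
  (convex, divergent as $r \to 1$): perfect instruments are unaffordable,
  which reflects practice. It is pluggable (`cost_model(reliability_cost=)`).
* **Objective**: minimize analytic false power subject to the budget, by
  exhaustive grid search (default 41 × 41 loadings × 20 sample sizes; the
  surface is cheap and can be flat, and an exactly reported optimum matters
  more than speed). Because a worthless exposure instrument
  ($\alpha_x = 0$) attains the nominal level trivially, ties are broken by
  lower cost, then lower n, then *higher* confounder loading, then higher
  exposure loading: among equally unbiased designs the search prefers the
  cheap, small study with the best-measured confounder. The
  counterintuitive headline survives in `allocation_report()`: under
  symmetric instrument prices the optimum never spends more on the exposure
  instrument than on the confounder instrument — sometimes the nuisance
  variable deserves the money.
* Power to detect a **true** direct effect is out of scope (the model
  family has no direct path), as are validation-substudy designs and
  measurement-error-correction estimators such as regression calibration.

## Known limitations

* Linear-normal models only; the results do not transfer to generalized
  linear models with non-linear links.
* One adjustment covariate; no correlated or differential errors; no
  treatment of the outcome being mismeasured.
* The noncentral-F false power treats the population partial correlation as
  the noncentrality driver — the standard population-level power
  approximation — rather than deriving the exact finite-sample distribution
  of the sample partial correlation under measurement error; the
  Monte Carlo agreement checks bound the practical error of that
  approximation at the sample sizes used.

## Reproducing the figures

`render_figure()` writes each canonical curve as CSV plus PNG; the CSVs are
the regression-tested artifact (byte-stable for a fixed version and grid).
The four canonical parameter sets are $(\gamma, \beta) = (0.64, 0.13)$ for
the Model-1 attenuation curve, $(0.19, 0.50)$ for the tied-reliability
curve with its interior maximum at $\alpha^* \approx 0.597$, and
$\beta = \gamma = 1$, $\omega = -1$ for the linked-loadings curve and its
derivative.

```{r figures, eval = FALSE}
render_figure("model2_constrained_bias", out_dir = "figures")
critical_point(beta = 0.5, gamma = 0.19)
```
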