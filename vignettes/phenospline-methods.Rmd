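---
title: "Two-stage spatio-temporal modelling of HTP time series: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage spatio-temporal modelling of HTP time series: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenospline)
```

This vignette is the package's own account of the statistical machinery: the
two models, their assumptions, the tunable parameters, the numerical choices,
and what the simulation-based tests do and do not establish.

## The problem

A high-throughput phenotyping experiment observes a low-level trait
$y_{pgi}(t)$ on plant $i$ of genotype $g$ in population $p$, at common times
$t_1 < \dots < t_n$, with each plant sitting at a fixed (row, column)
position on a grid. Three nuisance processes sit between the data and the
genetic signal: a smooth spatial trend that differs between measurement
times, experimental-design factors, and measurement error. The goal is
genotype- and population-level growth curves, their derivatives, and
time-independent traits derived from them, with honest uncertainty.

Missing records are allowed at both the plant and the genotype level; they
are carried as explicit empty slots so the plant-by-time array structure is
never lost.

## Stage 1: spatial correction per time point

At each time the package fits a spatial mixed model: fixed intercept,
population effects (reference coding) and any "average-over" design factors;
random row effects, column effects, "random"-role design factors, genotype
effects with one genetic variance per population, and a two-dimensional
P-spline surface over the grid. The surface uses the PS-ANOVA decomposition:
a fixed polynomial part $\{1, u, v, uv\}$ and five random smooth blocks —
$f(u)$, $f(v)$, $u\,\mathrm{smooth}(v)$, $\mathrm{smooth}(u)\,v$ and
$\mathrm{smooth}(u)\,\mathrm{smooth}(v)$ — each with its own variance
parameter. The smooth-by-smooth block uses nested marginal bases of half
dimension, following platform practice where the marginal bases take one
basis function per row/column. Each smooth block is column-centred,
orthogonalised against the polynomial part, and rescaled to mean unit column
norm; the rescaling is an equivalent reparameterisation that keeps all
variance parameters on comparable scales and markedly improves the REML
fixed point's conditioning.

The corrected phenotype keeps the intercept, the population (and
condition-factor) effects, each averaged design factor at the mean of its
level effects, the genotype BLUPs, and the residual. It deliberately keeps
the residual so that stage 2 works at plant resolution; shrinkage of the
genotype BLUPs is counteracted by that residual, which is why modelling
genotypes as fixed or random yields nearly identical corrected values (the
test suite asserts correlation above 0.99 on simulated data).

Uncertainty travels to stage 2 through precision weights
$w(t) = \mathrm{diag}\{(\mathrm{vcov}(\hat p(t)) + \hat\sigma^2_t I)^{-1}\}$,
where $\mathrm{vcov}(\hat p)$ is the joint fixed-estimate variance and
random-effect prediction error variance of the kept terms, obtained from the
inverse Henderson matrix. The full matrix is inverted (not just its
diagonal reciprocals), at a cost of one dense $M_t \times M_t$ inverse per
time point.

Two caveats are worth stating. First, because the polynomial part of the
surface is always present and always removed, the correction is not an exact
identity even when the data contain no spatial trend at all — a small part of
genuine plant-level variation is absorbed. Second, genotypes entirely
unobserved at a time point receive a shrunken (zero) BLUP but no residual,
so their plants' corrected values stay missing at that time.

## Stage 2: three-level P-spline growth model

The corrected series are modelled additively:
$\tilde y_{pgi}(t) = f_p(t) + f_{pg}(t) + f_{pgi}(t) + \varepsilon_{pgi}(t)$.
Each function is a cubic B-spline with a second-order difference penalty,
written in mixed-model form: an intercept and slope plus $b - 2$ random
columns carrying an identity penalty. Population intercepts and slopes are
fixed; genotype and plant intercepts and slopes are independent random
effects (diagonal covariance — no intercept–slope correlation, matching the
model's stated covariance structure), and each level's smooth coefficients
are i.i.d. with their own variance. Populations get one smooth variance
each; genotype-level variances (intercept, slope, smooth) can be shared or
per population; plant-level variances are shared by default with a
per-genotype option. The resulting design has exactly
$k\,b_{pop} + L\,b_{gen} + M\,b_{plant}$ columns, which the constructor
asserts.

### The mixed-model reparameterisation

The package derives the random columns by the spectral decomposition of the
penalty $D^\top D$: columns $B U_+ \Lambda_+^{-1/2}$ for the eigenvectors
with positive eigenvalues. Knots are equally spaced and extended degree-fold
beyond each boundary, so the Greville abscissae are linear in the coefficient
index and the penalty null space maps exactly onto $\{1, t\}$; with
boundary-replicated knots this correspondence — and with it the exact
equivalence between the penalised fit and the mixed-model fit — would fail
near the boundaries. The linear covariate is rescaled to $[0, 1]$ for
numerical balance. Fitted deviations are mapped back to raw B-spline
coefficients (intercept + slope via the Greville abscissae, smooth part via
the inverse transform), which is what makes the deviation areas exact spline
integrals rather than quadrature approximations.

### REML engine

Estimation solves Henderson's equations with a sparse Cholesky factorisation
(fill-reducing permutation, symbolic factor reused across iterations is not
needed at the tested sizes) and iterates the Harville fixed point:
$\sigma_g^2 \leftarrow \hat u_g^\top \hat u_g / ED_g$ with the effective
dimension $ED_g = q_g - \mathrm{tr}([C^{-1}]_{gg}) / \sigma_g^2$, and
$\sigma^2$ from the weighted residual sum of squares over
$N - \mathrm{rank}(X) - \sum_g ED_g$. The $-2$ REML log-likelihood is
computed from the same factorisation
($N\log\sigma^2 - \sum\log w_i + \log|G| + \log|C| + y^\top P y$, constant
omitted) and is verified in the tests against a dense-matrix oracle and a
brute-force numeric optimiser.

Numerical choices: convergence requires relative deviance change below
$10^{-8}$ and maximum relative variance change below $10^{-6}$, within 200
iterations; variance components are floored at $10^{-10}\,\mathrm{var}(y)$
and reported when pinned. Components that collapse toward zero decay
geometrically and are excluded from the variance-change criterion once below
$10^{-6}\,\mathrm{var}(y)$ — they no longer influence the fit, and waiting
for them to hit the floor would only burn iterations. Non-convergence
returns the last iterate with a warning rather than failing, and stage 1
records such time points in its log. Rank-deficient fixed parts drop
trailing dependent columns with a warning. All variance components start at
$\mathrm{var}(y)/(\#\mathrm{groups}+1)$.

### Weights: two readings

Stage 1 defines $w$ as an inverse variance, so the default residual
covariance in stage 2 is $\sigma^2\,\mathrm{diag}(1/w)$ — larger weight,
smaller residual variance. The model statement can also be read literally as
$\sigma^2\,\mathrm{diag}(w)$; `hier_config(weight_mode = "variance")`
implements that reading. Both are tested; the default is the precision
reading because it is the only one consistent with how the weights are
constructed.

### Curves, bands, derivatives, traits

Curves at any level are sparse linear maps of the coefficient vector;
pointwise standard errors are square roots of $L C^{-1} L^\top$ diagonals
(prediction error variance), and 95% bands use the normal multiplier 1.96.
Genotype curves are population curve plus deviation by construction, and the
tests assert this additivity to machine precision. First derivatives apply
the derivative basis (degree reduction) to the same coefficients, so
derivative bands come from the same machinery. The default evaluation grid
has 401 equally spaced points.

Trait extraction refines grid extrema by three-point quadratic
interpolation, which locates interior extrema to well below one grid step;
endpoints are never reported as local extrema, and windows without an
interior maximum fall back to the windowed grid maximum with a flag.
Deviation areas are exact integrals of the deviation spline via the
antiderivative construction. Estimated first derivatives are noticeably more
sensitive to the basis dimension than the curves themselves — windows for
maximum growth rates are therefore a user decision, shipped only as example
configuration.

## The synthetic-data generator

`simulate_experiment()` draws from the same generative family the stage-2
model assumes: logistic population curves (with a positive baseline, since
real assays measure established plants), genotype and plant deviations as
random intercept + slope + smooth B-spline draws, a smooth spatial surface,
optional two-level design factor allocated by grid half, heteroscedastic
Gaussian noise, and missing records at a configurable rate. The spatial
surface is an additive mix of low-frequency row and column gradients plus a
weaker smooth interaction, with drifting amplitude and phase — platform
trends are dominated by marginal temperature/light/soil gradients, and a
pure product surface with zero marginals would be an adversarial corner
case rather than a realistic one. All draws derive deterministically from
one seed through fixed per-component sub-seeds.

Defaults describe a compact greenhouse study: 2 populations × 10 genotypes
× 4 plants (M = 80) on a 10 × 8 grid, 15 times over DOY 100–135, logistic
plateaus of 100 and 140 units above a baseline of 20, genotype variances
(16, 25, 4) and plant variances (4, 4, 1) on the unit-scaled time, surface
amplitude 8, design-factor effect 3, residual SD 2 with a 30% linear drift,
5% missingness.

What passing tests on these data show: the solvers agree with dense oracles;
the pipeline removes spatial trends it models well, recovers variance
components without material bias, and produces curve bands with close to
nominal coverage when the generating process matches the model. What they do
not show: robustness to non-Gaussian error, to spatial structure outside the
smooth-plus-factor family (e.g. abrupt platform faults), to strongly
irregular measurement times, or to misspecified hierarchies — real platform
data contain all of these to some degree.

## Simulation conditions used by the test suite

The recovery and coverage checks simulate at 2 populations × 10 genotypes ×
4 plants, n = 15 times, with matched generation and analysis bases of
dimension 9 — a deliberately generous basis, following the recommendation to
let the penalty, not the basis size, control smoothness; with a visibly
coarser basis the smoothing bias on the fixed logistic population curve
depresses band coverage below nominal. Variance-component recovery averages
estimates over 20 replicates (a bias check; per-replicate variance estimates
from 20 genotype-level draws have a sampling CV near 32% regardless of the
estimator's quality). Coverage pools 200 replicates of genotype-curve bands
on an 11-point grid. The larger platform configurations are exercised for
design bookkeeping only; fitting them is routine (minutes) but not part of
the default test run.

## Known limitations

- Stage 1 shares no information across time points by design; times where
  the per-time fit fails are left missing rather than interpolated.
- The Harville fixed point is robust but can be slow when a variance
  component is weakly identified (large value, tiny effective dimension);
  the block rescaling mitigates this, and persistent cases return the last
  iterate with a warning.
- Confidence bands are plug-in: variance-component uncertainty is not
  propagated, which costs a few points of coverage in small experiments
  (few populations especially).
- Crossed (non-nested) grouping structures, separable autoregressive
  spatial models and array-algorithm (GLAM) acceleration are out of scope;
  panels × treatments are handled by crossing them into "populations", as
  in the shipped examples.
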