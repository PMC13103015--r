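---
title: "Screening longitudinal biomarker panels against cardiac function with bivariate mixed models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening longitudinal biomarker panels against cardiac function with bivariate mixed models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trajscreen)
```

## The scientific problem

After a myocardial infarction, cardiac structure and function keep evolving
for months: atrial and ventricular volumes tend to dilate while ejection
fraction partially recovers. High-throughput proteomics makes it possible to
measure thousands of circulating proteins at the same follow-up visits, and
the natural question is which protein *trajectories* travel together with the
*trajectories* of cardiac function — not merely which baseline levels
correlate with a later outcome.

`trajscreen` addresses this with a pairwise joint-modeling screen. Each
(protein, echocardiographic variable) pair is modeled with a bivariate linear
mixed-effects model whose patient-level random effects are allowed to be
correlated across the two outcomes. The screen asks, for every pair, whether
that cross-outcome correlation is zero.

## The model

For patient $i$, outcome $k \in \{P, E\}$ (log-protein and echo variable)
and visit time $t$ in months,

$$y_{ik}(t) = x_{ik}(t)^\top \beta_k + z_{ik}(t)^\top b_{ik} +
\varepsilon_{ik}(t),$$

* $x_{ik}(t)$ holds an outcome-specific intercept, age (years), a sex
  indicator (female = 1), and a 2-df natural cubic spline in $t$;
* $z_{ik}(t)$ is the outcome's random-effect design — intercept only
  ($q=1$), intercept + linear slope ($q=2$), or intercept + the 2-df spline
  ($q=3$);
* $b_i = (b_{iP}, b_{iE}) \sim N(0, D)$ with $D$ of dimension $q_P + q_E$;
* $\varepsilon_{ik}(t) \sim N(0, \sigma_k^2)$, independent across
  observations and of $b_i$, with outcome-specific residual variances
  (the outcomes live on unrelated scales).

The *full* model leaves $D$ unstructured (positive definite). The *null*
model forces the cross-outcome block to zero,
$D = \mathrm{blockdiag}(D_P, D_E)$. Both are fitted by maximum likelihood
and compared with

$$\Lambda = 2(\hat\ell_{\text{full}} - \hat\ell_{\text{null}})
\;\sim\; \chi^2_{q_P \cdot q_E}.$$

The constrained parameters are covariances (interior points of the parameter
space), not variances, so the usual boundary-mixture correction does not
apply. ML rather than REML is used throughout: the fixed-effects design is
identical under both hypotheses, and ML keeps the likelihood comparison
unambiguous.

Across a panel of proteins the resulting p-values are adjusted with the
Benjamini–Hochberg step-up procedure, by default within each echo variable's
family (a config flag pools all pairs into one family instead); pairs are
declared significant at FDR < 0.05.

Because spline random effects carry no readily interpretable direction, the
sign of each association is summarized separately by the Spearman rank
correlation, across patients, of within-patient mean log-protein versus
within-patient mean echo values, with a Fisher-z interval
($\mathrm{se} = \sqrt{1.06/(n-3)}$).

## Time basis

All time trends use natural cubic splines with two degrees of freedom:
boundary knots at the minimum and maximum observed measurement times of the
variable at hand, one interior knot at the median of its observation times
(with multiplicity). Knots are placed per variable because the two visit
grids differ — echo at discharge (0), 3 and 12 months; proteins at 1, 3 and
12 months, baseline protein samples being excluded as acute-phase artifacts.
The basis is built by `splines::ns()`; any basis spanning the same space
gives the identical model fit (the likelihood is invariant to invertible
linear reparameterizations of the basis, and the tests assert exactly that
property rather than basis coordinates). Beyond the boundary knots the
spline continues linearly. When a variable has only two distinct times the
fixed time basis degrades to a single linear term, and to none with a single
time.

## Fitting and the convergence contract

The marginal likelihood is evaluated per patient through the Woodbury
identity, factorizing only $q \times q$ systems (a compiled kernel);
patients observed on a single outcome simply contribute no cross-block
information. Fixed effects are profiled out by generalized least squares,
and the remaining parameters — $\log\sigma_P^2$, $\log\sigma_E^2$ and a
log-Cholesky factor of $D$ (one joint block for the full model, two blocks
for the null) — are optimized with `nlminb`. The log-Cholesky map keeps $D$
positive definite without constraints.

A fit counts as converged only when all of the following hold:

* the optimizer reports success;
* the relative gradient norm (central differences) is below `tol`
  (default `1e-4`);
* the log-likelihood is finite and $\mathrm{cond}(D) < 10^{10}$;
* the numeric Hessian of the profiled objective is positive definite, with
  smallest eigenvalue above $10^{-4}$ of the largest.

The Hessian clause is what operationalizes "unable to converge": on a
likelihood ridge — e.g. a spline random block whose marginal covariance the
3-point visit grid cannot separate from $\sigma^2$, or a variance component
estimated at zero — the gradient vanishes along the flat direction, so a
gradient test alone would happily accept a non-identified optimum. Two
random restarts (seeded, jittered starts) are attempted before declaring
failure, except on a detected ridge, which no restart can repair. The null
model is always fitted first and its solution, embedded exactly into the
full parameterization (the Cholesky factor of a block-diagonal matrix is
block-diagonal), is one of the full model's starting points; this guarantees
$\hat\ell_{\text{full}} \ge \hat\ell_{\text{null}}$.

### The fallback ladder

Pairs are fitted along a ladder of structure pairs, starting at
(spline, spline) and dropping in total dimension down to
(intercept, intercept); asymmetric combinations are included, and within a
tier the protein side is reduced first (an arbitrary but fixed and
configurable order). The first candidate whose full *and* null fits both
satisfy the contract is used for the test. Spline candidates are skipped
outright for a variable with fewer than 3 distinct observation times, slope
candidates below 2. If nothing converges the pair is reported with
`converged = FALSE`, carries no p-value, and is excluded from the BH family
(the family size is the number of converged pairs — logged prominently by
`runScreen`).

## The synthetic cohort generator

Real post-MI cohorts of this design are not publicly available, so the
package ships a generator that draws cohorts from exactly the model above
with known ground truth: 246 patients by default, ages Uniform(40, 80),
19% women, echo variables AV and LVEDV (mL/m²) and LVEF (%) on the 0/3/12
month grid, proteins on the 1/3/12 month grid, visit-level missingness
(default 5%). Default echo anchor means (AV 20.5 → 24.6 → 25.4; LVEDV
52.3 → 59.4 → 62.3; LVEF 49.3 → 53.9 → 55.2) mimic the qualitative
post-infarction pattern of dilating volumes and recovering ejection
fraction; random-intercept SDs (5.5, 13, 7.5) and residual SDs (2.5, 6, 4)
are on the order of the clinical between- and within-patient spread of the
respective measures. Proteins are generated on the log scale (intercept SD
0.35, residual SD 0.25, a mild upward trend around a log-level of 7) and
exponentiated on output so the pipeline's log-transform runs end to end.
"True" proteins couple to their target echo variable through correlated
random intercepts ($\rho$); the joint covariance is checked for positive
semi-definiteness before any sampling. `makeNullConfig()` zeroes every
cross-block for calibration runs.

What the generator deliberately does *not* emulate: assay artifacts (batch
effects, aptamer cross-reactivity, hook effects), informative dropout,
irregular per-patient visit times, or residual correlation between outcomes
measured at the same visit. Passing tests therefore demonstrate the
statistical machinery under the stated model, not robustness to those
real-data complications.

## Simulation scales and what the tests compute

The test suite and `scripts/acceptance.R` recompute, from scratch:

* **Likelihood oracle** — the Woodbury evaluation agrees with a dense
  multivariate-normal density on 50 random small instances to 1e-8.
* **Null calibration** — 500 replicates under a block-diagonal truth
  (RI/RI, n = 150, complete 3-visit grids): empirical rejection at
  $\alpha = 0.05$ must land in [0.030, 0.075].
* **Parameter recovery** — 100 replicates at n = 300, $\rho = 0.6$: median
  $|\hat\rho - 0.6| \le 0.08$; residual variances and the population
  trajectory values within 10% relative error.
* **Screen FDR/recall** — six seeded replicates of a 50-protein screen
  (10 true pairs at $\rho = 0.7$, n = 250): mean empirical FDR ≤ 0.10 and
  recall ≥ 0.8 at q < 0.05. These screens configure the ladder to the
  generative (RI, RI) structure; walking the full ladder on every null
  protein exercises nothing further and multiplies runtime roughly
  twenty-fold.
* **Determinism** — the generate → transform → screen → write pipeline is
  bitwise reproducible under a fixed seed.

These replicate counts keep the whole suite in the tens of minutes on a
single core while leaving the binomial/Monte-Carlo error comfortably inside
each acceptance band.

## Numerical and design choices worth knowing

* **Log base.** Proteins are transformed with the natural log, conventional
  for relative-fluorescence assay units; the LRT is invariant to the base.
* **Sex coding.** Female = 1 in all designs; fixed and documented,
  arbitrary otherwise.
* **Covariate handling in population curves.** Population-average
  trajectories (`fitUnivariateTrajectory`) evaluate covariates at the
  sample mean age and sex proportion; the reported modeled SD is the
  *marginal* SD, $\sqrt{z(t)^\top D z(t) + \sigma^2}$, i.e. it includes the
  residual contribution.
* **Paired change tests** use raw measurements matched to nominal visits
  within ±0.5 months (configurable), not modeled values.
* **Degenerate inputs.** Zero-variance differences, fewer than 2 complete
  pairs, fewer than 3 patients for a Spearman summary, non-positive protein
  values, duplicated (patient, time, variable) rows and missing covariate
  rows all raise immediate, specific errors rather than propagating NaNs.
* **FDR family.** Per-echo families by default (matching how per-protein
  FDR is naturally reported within each echo variable); a pooled family is
  one config flag away.
* **Non-converged pairs** reduce the BH family size. This is a deliberate,
  visible choice: no p-value exists for them, and pretending otherwise
  (e.g. p = 1) would distort the family.

## Known limitations

* The $\chi^2$ reference for the LRT is asymptotic; at small n (tens of
  patients) the test can be mildly conservative or liberal. The null
  calibration property guards the regime the screen targets
  (n ≈ 150–250).
* Residuals of the two outcomes at a shared visit are assumed independent
  given the random effects; a same-day measurement correlation would be
  absorbed into the cross-outcome random-effect correlation.
* The ladder's reduction order is a convention. Data that identify an
  asymmetric rich structure will use it, but ties between orders are
  resolved by position in the ladder, not by model comparison.
* Spearman confidence intervals use the Fisher-z approximation, adequate
  at the cohort sizes targeted here; a bootstrap would be preferable below
  a few dozen patients.
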