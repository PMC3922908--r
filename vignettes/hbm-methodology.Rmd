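---
title: "Methodology: second-order CFA scoring of Health Belief Model questionnaires"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methodology: second-order CFA scoring of Health Belief Model questionnaires}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hbmscore)
```

## The model

The package models a 22-item, 5-point-Likert Health Belief Model (HBM)
questionnaire with five first-order constructs — perceived susceptibility
(SUS, items 1–5), perceived seriousness (SER, 6–9), perceived benefits
(BEN, 10–14), perceived barriers (BAR, 15–18) and cues to action
(CTA, 19–22) — driven by a single second-order health-belief factor (HB).

The measurement model is

$$y = \Lambda \eta + \varepsilon, \qquad
\eta = B\eta + \gamma\,\xi + \zeta,$$

where $\xi$ = HB with $\mathrm{Var}(\xi) = 1$, $\Lambda$ is the
$22 \times 5$ simple-structure loading matrix, $\gamma$ holds the five
second-order coefficients, and $B$ carries the single structural path
BAR → CTA with coefficient $\beta$. Disturbances $\zeta$ and
uniquenesses $\varepsilon$ are mutually independent normals. The implied
covariance is

$$\Sigma(\theta) = \Lambda \Phi \Lambda^\top + \Theta,
\qquad
\Phi = (I - B)^{-1}\,(\gamma\gamma^\top + \Psi)\,(I - B)^{-\top},$$

with $\Psi = \mathrm{diag}(\psi)$ the disturbance variances and
$\Theta = \mathrm{diag}(\theta)$ the uniquenesses.

### Assumptions

- Multivariate-normal latent variables and errors; ordinal responses are
  treated as discretizations of an underlying continuum (the generator)
  but are analysed with normal-theory ML on their product-moment
  covariance (the engine), a standard and deliberately simple choice.
- Simple structure: every item loads on exactly one factor; no
  correlated uniquenesses.
- The only deviation from a pure second-order structure is the single
  BAR → CTA path; the structural matrix must be acyclic (checked).
- Missingness, when simulated, is missing-completely-at-random (MCAR);
  estimation uses listwise deletion, matching that mechanism.

## Estimation

`hbm_cfa()` minimizes the ML discrepancy

$$F_{\mathrm{ML}} = \ln|\Sigma| + \mathrm{tr}(S\Sigma^{-1}) - \ln|S| - p$$

over the free parameters. Identification fixes the first loading of each
factor to 1 (marker variables) and $\mathrm{Var}(\mathrm{HB}) = 1$;
variances are optimized on the log scale so they stay positive without
constraints. The full model has 50 free parameters and
$p(p+1)/2 - 50 = 203$ degrees of freedom.

Numerical choices:

- **Analytic gradients** for every parameter block (loadings, $\gamma$,
  $\beta$, log-disturbances, log-uniquenesses), verified against finite
  differences in the test suite. BFGS (`stats::optim`, `reltol = 1e-14`)
  with a polish loop that restarts from the current optimum until the
  gradient norm is at most `1e-6`.
- **Multiple starts**: data-driven starting values from the marker-item
  covariances, jittered per start; the best converged minimum is kept.
  Jitter-invariance of the reported optimum is tested.
- **Sign indeterminacy** of HB is resolved by requiring
  $\sum_k \hat\gamma_k > 0$; marker loadings pin the first-order factor
  signs. Under the benchmark structure this leaves BAR's coefficient
  negative, as substantively expected.
- **Heywood screening**: fits whose standardized loadings or variance
  parameters sit essentially on the boundary are flagged
  (`fit$heywood`), not silently accepted.
- $\chi^2 = (n-1)\,F_{\mathrm{ML}}$; RMSEA confidence limits invert the
  noncentral-$\chi^2$ distribution with `stats::pchisq(ncp = )` and
  `uniroot`. GFI/AGFI use the ML weight matrix; NFI/CFI/IFI use the
  independence (diagonal) null model. For just-identified models
  (df = 0) the indices are undefined and reported as `NULL`.
- An **independent oracle** — a second ML-CFA minimizer with a different
  parameterization (standardized loadings plus a row-normalized
  correlation Cholesky) and numerical gradients, living entirely in the
  test helpers — agrees with the engine to well under `1e-3` on random
  instances, and to closed-form solutions on just-identified models.

## Standardization, total effects and scores

The standardized solution rescales each loading by
$\lambda^*_i = \lambda_i\,\mathrm{sd}(F_{k(i)})/\mathrm{sd}(y_i)$,
each second-order coefficient by $\gamma^*_k = \gamma_k/\mathrm{sd}(F_k)$
and the structural path by
$\beta^* = \beta\,\mathrm{sd}(\mathrm{BAR})/\mathrm{sd}(\mathrm{CTA})$.
The total effect of HB on factor $k$ is
$\mathrm{te} = (I - B^*)^{-1}\gamma^*$ — for CTA this composes the direct
path with the indirect route through BAR — and the per-item total effect
(the **CFAWS weight**) is $W_i = \lambda^*_i\,\mathrm{te}_{k(i)}$.
Barrier items therefore carry negative weights automatically.

Two scores are computed on the raw 1–5 responses:

- **CFAWS** (CFA-weighted score): $\sum_i W_i\,y_i$.
- **SSS** (simple summated score): unit weights, with BAR items
  subtracted rather than added.

Cohorts are compared with two-sample t-tests (`stats::t.test`), pooled
variance by default with Welch as an option. One consequence worth
knowing: under the pooled test, the confidence-interval width measured
in pooled-SD units is $2\,t_{crit}\sqrt{1/n_1 + 1/n_2}$ for *any* linear
score, so CFAWS and SSS tie exactly on that scale; CFAWS's advantage
shows up in effect-size terms (a larger standardized mean difference per
unit of latent shift), which the calibration tests exercise.

## The synthetic-data generator

`hbm_generator_config()` fixes $\gamma$, $\beta$, standardized loadings
$\lambda$, cohort sizes, the intervention shift $\delta$ (added to the
HB mean of the post cohort), discretization thresholds, response scale,
and MCAR missingness rate. Disturbance variances are solved so every
first-order factor has unit variance, making the supplied $\lambda$,
$\gamma$, $\beta$ directly the standardized truth. All randomness flows
from a single integer seed; cohort and missingness draws use small fixed
offsets of it, and the generator restores the caller's RNG state.

`hbm_benchmark_config()` provides the default study conditions:
$\gamma = (0.72, 0.84, 0.87, -0.18, 0.60)$, $\beta = 0.35$, loadings
derived from a reference per-item total-effect table as
$\lambda_i = W_i / \mathrm{te}_{k(i)}$, cohort sizes 843 (pre) and 1269
(post), thresholds $(-1.5, -0.5, 0.5, 1.5)$, and $\delta = 0.33$.

Two defaults deserve explanation:

- **The item-22 loading is capped at 0.99.** The reference total-effect
  table, taken at face value, implies $\lambda_{22} = 0.54/0.537 > 1$
  — an artifact of two-decimal rounding in the table, and inadmissible
  for a generator that needs $1 - \lambda^2 > 0$. The cap changes item
  22's implied weight to 0.532, within every recovery tolerance used.
- **$\delta = 0.33$.** Closed-form algebra under the benchmark
  parameters gives a standardized SSS effect of about $0.90\,\delta$, so
  $\delta = 0.33$ produces a standardized mean difference near 0.3 — a
  moderate, realistically detectable programme effect at these cohort
  sizes.

### Realism and limits

The generator captures the covariance structure, ordinal coarsening,
cohort imbalance and MCAR missingness of a real pre/post study. It does
*not* model item-level method effects, differential item functioning
between cohorts, non-normal latent distributions, informative
missingness, or clustering by school/class. Ordinal discretization with
the default thresholds attenuates product-moment covariances slightly
relative to the continuous truth (quantified in the tests), which is why
large-sample recovery checks use the continuous response scale.

## Problem sizes used in validation

The test suite fits the full model at $n$ up to 50,000 (recovery of all
standardized coefficients and total effects within $\pm 0.02$), runs
repeated-fit calibration studies (bias/RMSE of $\hat\gamma^*,
\hat\beta^*$ at $n = 5000$; mean $\chi^2 \approx$ df under a true
model), checks null-calibration of the cohort comparison over hundreds
of replicate studies at $\delta = 0$, and cross-validates against the
independent oracle and closed-form solutions. `scripts/acceptance.R`
reproduces the headline recovery numbers from scratch against the
installed package.

## Limitations

- Normal-theory ML on ordinal data is pragmatic, not optimal;
  polychoric-based or weighted-least-squares estimation would respect
  the response scale better but is out of scope.
- Listwise deletion is only defensible under MCAR, which the generator
  guarantees but real data may not.
- Standard errors and parameter-level inference for the CFA estimates
  are not provided; the package's inferential targets are the cohort
  comparisons.
- CFAWS weights are estimated on the same data they score when used
  within one study; with small samples this reuses sampling noise.
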