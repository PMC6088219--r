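---
title: "Quantile structural equation models for latent psychological outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantile structural equation models for latent psychological outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Psychological-problem scores in occupational cohorts are typically
right-skewed: most employees report few symptoms, a minority report many.
A mean-regression structural equation model (SEM) then describes only the
center of the outcome distribution and can misstate how stressors relate
to the employees who matter most for prevention — those in the upper tail.
`quantsem` implements the alternative this package is built around: a
**Bayesian quantile SEM** in which a chosen quantile of a *latent*
response is regressed on latent predictors and fixed covariates.

The intended application is a cross-sectional occupational-health design:

* three observed psychological-problem indicators — GHQ-12 psychological
  distress (bimodal 0-0-1-1 scoring, range 0–12), HADS anxiety and HADS
  depression (each 0–21, caseness at ≥ 8) — measuring one latent
  *psychological problems profile* $\eta$;
* eleven stressful-life-event (SLE) domain scores (each the mean of its
  0–5 intensity items) measuring two latent stressor domains:
  *socioeconomic* (financial, social relations, personal conflict, job
  conflicts, educational, job security, daily life) and *personal* (home
  life, loss and separation, sexual life, health concerns);
* fixed covariates entering the structural equation error-free: age, sex,
  marital status, education (reference: under 6 years), household size,
  shift work, sleep duration, smoking, BMI, physical activity (IPAQ
  MET-h/week) and the effort–reward imbalance ratio.

## Model

Measurement (indicators $y_{ij}$, latent states
$\omega_i = (\eta_i, \xi_{i1}, \xi_{i2})$):

$$y_{ij} = \mu_j + \lambda_j \,\omega_{i, f(j)} + \varepsilon_{ij},
  \qquad \varepsilon_{ij} \sim N(0, \psi_j),$$

block-sparse: each indicator loads exactly one factor, and the first
indicator of each factor is an *anchor* with $\lambda = 1$, which fixes
the latent scales (the alternative, unit factor variances, would put the
structural coefficients on an arbitrary scale; anchoring keeps them on
the indicator scale and is the common SEM convention).

Structural part, for a chosen quantile level $\tau$:

$$\eta_i = b^\top x_i + \gamma_1 \xi_{i1} + \gamma_2 \xi_{i2} + \delta_i,
  \qquad \delta_i \sim \mathrm{ALD}(0, \sigma, \tau),$$

with $\xi_i \sim N(0, \Phi_\xi)$. The asymmetric Laplace density
$f(u) = \tau(1-\tau)/\sigma \cdot \exp\{-\rho_\tau(u)/\sigma\}$ has the
check loss $\rho_\tau(u) = u(\tau - 1[u<0])$ as its negative
log-kernel, so maximizing this working likelihood is equivalent to
minimizing check loss: the fitted structural equation describes the
$\tau$-th conditional quantile of the latent profile. The ALD has **no
free location parameter** — its $\tau$-quantile is pinned at zero — which
is what identifies the structural location against the free indicator
intercepts; consequently the covariate design carries no intercept
column.

### Gibbs sampling

The ALD admits the normal–exponential mixture
$\delta = k_1 e + k_2\sqrt{\sigma e}\, z$ with $e \sim$ Exp(mean
$\sigma$), $z \sim N(0,1)$, $k_1 = (1-2\tau)/(\tau(1-\tau))$,
$k_2^2 = 2/(\tau(1-\tau))$. `ald_mixture_density()` verifies this
representation against the closed form by quadrature; the equivalence is
part of the test suite. Conditional on $e_i$ everything is Gaussian, so
the sampler (`gibbs_fit()`, implemented in C++) cycles exact conjugate
updates:

1. $e_i$ from its GIG$(1/2, \chi_i, \zeta)$ conditional, drawn exactly via
   the reciprocal inverse-Gaussian representation (the $\lambda = 1/2$
   case has a closed-form sampler; $e_i$ floored at $10^{-12}$);
2. $\omega_i$ from a trivariate normal (measurement $\times$ structural
   precision);
3. intercepts/loadings row-wise from conjugate normals, anchors held at 1;
4. $\psi_j$ from inverse-gamma;
5. $(\gamma, b)$ jointly from a multivariate normal (weighted by $1/e_i$);
6. $\sigma$ from its inverse-gamma conditional (shape $a_0 + 3n/2$);
7. $\Phi_\xi$ from inverse-Wishart.

Priors (all configurable): $N(0, 10^2)$ on free loadings, intercepts,
$\gamma$ and $b$; IG$(0.01, 0.01)$ on $\psi_j$ and $\sigma$;
IW$(I, 4)$ on $\Phi_\xi$ — weakly informative on standardized indicators
(indicators are z-scored before fitting by default; the scaling is
recorded in the fit object).

Each quantile level is fitted independently; no non-crossing constraint
is imposed, and crossing of the fitted quantile paths is reported as a
diagnostic (`fit_all_quantiles()$crossing`), not prevented.

Defaults are 2 chains × 6000 iterations with 2000 burn-in; summaries
carry split-$\hat R$ and an autocorrelation-based effective sample size.
The structural location direction (absorbed between the $\eta$-indicator
intercepts and the ALD asymmetry) mixes slowest, especially at extreme
$\tau$; the structural coefficients themselves mix much faster. For the
analyses shipped under `analysis/` (cohort of 3063) and in the tests
(cohorts of 150–2000) we use 2 × 4000 (burn-in 1500) or smaller, which
gives split-$\hat R < 1.05$ on the structural coefficients; these problem
sizes are the package's documented choices, stated here once rather than
in each script.

### Diagnostics with a latent response

Two calibration quantities deserve a note:

* **Residual sign fraction.** An exact check-loss minimizer leaves a
  fraction $\tau$ of residuals negative. The latent analogue holds for
  the *posterior expected* sign fraction — the average over draws of each
  draw's fraction of negative structural residuals — which is what
  `residual_sign_fraction()` reports by default. The fraction of negative
  *posterior-mean* residuals is not calibrated: shrinkage of the latent
  states compresses the residual distribution toward its center, so that
  variant (available as `method = "posterior_mean"`) understates tail
  calibration by construction.
* **Posterior predictive p-value.** For each retained draw a replicate
  dataset is simulated from the fitted model and a discrepancy is
  compared between replicate and observed data; values near 0.5 indicate
  plausibility. The default discrepancy is the sum of (i) the
  likelihood-ratio ($F_{ML}$) statistic of the indicator residual
  covariance against the model-implied marginal covariance and (ii) twice
  the structural check loss over the ALD scale. The $F_{ML}$ form is
  deliberate: a pure quadratic (Mahalanobis) form is first-order blind to
  cross-block covariance the model cannot reproduce — precisely the
  signature of a suppressed latent association — whereas the
  log-determinant term detects it. Measurement-only and structural-only
  discrepancies are selectable.

## Factor construction

`extract_profile()` takes the dominant eigenvector of the 3 × 3
correlation matrix of the psych indicators (sign-fixed so higher score =
worse mental health) and returns unit-variance scores plus the percent of
total variance explained — the principal-component quantity, chosen
because "% of total variance" is what the extraction step is summarized
by; principal-axis alternatives were deliberately left out of scope.
For three equicorrelated indicators with correlation $r$ the closed form
is $100(1+2r)/3$, the identity used to calibrate the synthetic cohort.

`efa_stressors()` extracts components of the 11-domain correlation matrix
(eigenvalue > 1 rule with scree report under `"auto"`), varimax-rotates
(`stats::varimax`, Kaiser normalization), and assigns each domain to the
factor with the larger absolute rotated loading. Whether the original
analysis used domain sums or means, and which extraction algorithm, is
not recorded anywhere we could consult; domain means and PCA-style
extraction are this package's declared assumptions, and scale invariance
of the correlation-based analysis makes the sums/means choice immaterial
for the EFA itself.

`quartile_descriptives()` reproduces the familiar Table-1-style layout:
sample quartiles of the profile score (boundary ties to the lower
quartile), mean (SD) with one-way ANOVA for quantitative variables,
n (%) with chi-square for categorical ones (zero cells produce a warning
and a flag, not a failure; constants are reported as not applicable).

## The synthetic cohort

Because the study data are not deposited, `synthetic_truth()` +
`generate_dataset()` define the cohort all analyses run on. The defaults
*are* the study conditions, chosen once:

* $n = 3063$ (the realized cohort; the design size from
  `cochran_sample_size(0.1, 0.05, 0.01, round_to = 100)` is 3500);
* psych-block unique variances set so the three indicators are
  equicorrelated at $r = 0.6889$, making the profile factor explain
  79.26% of their variance;
* stressor-block loadings solved numerically (given the latent-predictor
  correlation 0.3) so the two-factor EFA explains 45.63% of total
  variance, with the 7/4 block pattern;
* $\gamma = (0.2, 0.8)$ — the personal domain dominating the
  socioeconomic one, a stylized (not estimated) echo of the reported
  coefficient ranges;
* structural error skew-normal with moment skewness 0.9 ("notably
  skewed"), sd 0.6; `make_skewed_profile()` retargets the skewness by
  numerically inverting the skew-normal (attainable range ±0.995) or ALD
  (±2) skewness formulas, holding the error sd fixed;
* covariate marginals shaped like the cohort's descriptives (age
  36.73 ± 7.30, 8.4% female, 90.1% married, 62.3% with > 12 years of
  education, 54.9% shift workers, …). The education split below 12 years
  is not published; 7.7% / 30.0% for < 6 / 6–12 years is our choice.

What the generator does *not* emulate: multi-stage cluster sampling and
survey weights (out of scope), bounded/discrete indicator supports by
default (indicators are continuous; `discretize_likert()` is opt-in
because the fitted measurement model treats indicators as continuous),
item-level missingness, and any dependence of the measurement error on
covariates. Passing tests on this cohort therefore demonstrate correct
recovery of the assumed data-generating structure, not robustness to
real-data violations of it.

## Numerical choices and edge cases

* `fit_quantreg()` solves observed-predictor quantile regression
  *exactly*: smoothed-loss continuation (softplus smoothing, bandwidth
  $10^{-1}$ to $10^{-8}$ of the residual scale) locates the optimum, a
  vertex polish interpolates $p$ observations, and LP dual feasibility
  ($X_B^{-\top}$ multipliers inside $[\tau-1, \tau]$) certifies global
  optimality. It is the in-package stand-in for an external LP solver and
  is validated against brute-force enumeration of all basic solutions.
  In the sampler-vs-LP concordance check the data are generated at a
  small error scale (ALD $\sigma = 0.1$, measurement noise 0.01): the
  check-loss surface is piecewise linear, and at larger noise its flat
  region exceeds the comparison tolerance, making the check
  uninformative about sampler correctness.
* `fit_mean_sem()` maximizes the conditional Gaussian likelihood via
  BFGS on sufficient statistics (log/log-Cholesky transforms keep
  variances and $\Phi_\xi$ admissible), from moment-based block-proxy
  starts, with one restart; Heywood cases are clamped at $10^{-6}$ with
  a warning. With a covariance matrix as input, the classic
  $F_{ML}$ discrepancy is minimized and $\chi^2 = (n-1) F_{ML}$ (the
  $(n-1)$ convention is recorded because conventions differ); with data
  and covariates, $\chi^2$ is the likelihood ratio against the saturated
  conditional model. The baseline for CFI/TLI is the independence model
  with free means and variances.
* Degenerate inputs: constant indicators are rejected in
  `extract_profile()`; a singular domain correlation matrix aborts with
  its condition number; an all-unit-eigenvalue spectrum flags the
  eigenvalue > 1 rule as degenerate rather than guessing; Likert
  thresholds must be strictly increasing and ties go to the upper bin.

## Limitations

Ordinal (probit-link) measurement models, oblique rotations,
survey-weighted estimation, simultaneous multi-$\tau$ estimation with
non-crossing constraints, and FIML missing-data handling are out of
scope. Coefficients at extreme quantiles ($\tau = 0.05, 0.95$) carry
visibly more posterior spread and, under misspecified error skewness,
some bias; the median and central quantiles are the best-identified part
of the model. The study's own coefficient values cannot be reproduced
because its data are unavailable; everything quantitative here is
property-based recovery on the synthetic cohort.
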