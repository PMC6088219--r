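# quantsem

Bayesian **quantile structural equation models** for latent psychological
outcomes, with the questionnaire scoring, factor construction, synthetic
data and model-checking machinery needed to run the full analysis as a
reproducible pipeline.

## The problem

In occupational mental-health studies, psychological-problem scores are
right-skewed: a mean-regression SEM describes the average employee and can
misrepresent how stressors relate to the highly symptomatic minority.
`quantsem` instead regresses chosen **quantiles of a latent response** on
latent predictors and fixed covariates:

- measurement: `y_ij = mu_j + lambda_j * omega_{i,f(j)} + eps_ij`,
  `eps ~ N(0, psi_j)`, one factor per indicator, anchor loadings fixed
  at 1 — three psychological indicators (GHQ-12 distress, HADS anxiety,
  HADS depression) measure the latent *psychological problems profile*
  `eta`; eleven stressful-life-event domain scores measure two latent
  stressor domains `xi` (socioeconomic: 7 domains; personal: 4);
- structural, at quantile level `tau`:
  `eta_i = b'x_i + gamma_1 xi_i1 + gamma_2 xi_i2 + delta_i` with
  `delta ~ ALD(0, sigma, tau)` — the asymmetric Laplace working
  likelihood whose negative log-kernel is the check loss
  `rho_tau(u) = u (tau - 1[u<0])`, so the fit targets the `tau`-th
  conditional quantile of the latent profile.

Estimation is by Gibbs sampling (C++): the ALD's normal–exponential
mixture `delta = k1 e + k2 sqrt(sigma e) z`, `e ~ Exp(mean sigma)`, makes
every full conditional conjugate (GIG mixing variables, normal latent
states and coefficients, inverse-gamma variances, inverse-Wishart latent
covariance). Each quantile in `{0.05, 0.25, 0.50, 0.75, 0.95}` is fitted
independently; coefficients come with equal-tailed 95% credible intervals
and a significance flag (interval excludes zero). A classical
mean-regression SEM (`fit_mean_sem`, with CFI/TLI/RMSEA) and a posterior
predictive p-value (`posterior_predictive_pvalue`, plausible near 0.5)
provide the comparison model and goodness of fit.

Because the motivating study's participant data are not public, the
package ships a synthetic-data generator (`synthetic_truth`,
`generate_dataset`) whose defaults are calibrated to the study's printed
structure (profile factor explaining 79.26% of its indicators' variance;
two stressor factors explaining 45.63% of total variance in a 7/4 block
pattern; skewed structural error), so every analysis, test and acceptance
number is computed against known ground truth.

## Worked example

```r
library(quantsem)

# design-stage sample size: prevalence 0.1, alpha 0.05, margin 0.01
cochran_sample_size(0.1, 0.05, 0.01, round_to = 100)
#> [1] 3500

# a synthetic cohort at the study scale with known truth
truth <- synthetic_truth(seed = 1)            # n = 3063, gamma = (0.2, 0.8)
sim <- generate_dataset(truth)

extract_profile(sim$indicators[1:3])$variance_explained
#> [1] 78.69

efa <- efa_stressors(sim$indicators[4:14])
efa$variance_explained
#> [1] 47.06
efa$assignment                                 # 7/4 block structure
#>         financial  social_relations personal_conflict     job_conflicts
#>                 1                 1                 1                 1
#>       educational      job_security        daily_life         home_life
#>                 1                 1                 1                 2
#>   loss_separation       sexual_life   health_concerns
#>                 2                 2                 2

# quantile SEM at the median (2 chains x 4000, burn-in 1500)
spec <- qsem_spec(
  eta_indicators = c("ghq12_distress", "hads_anxiety", "hads_depression"),
  xi_indicators  = list(socioeconomic = stressor_domains()$socioeconomic,
                        personal      = stressor_domains()$personal),
  covariates     = design_columns(),
  mcmc = list(chains = 2L, iter = 4000L, burnin = 1500L))
dat <- cbind(sim$indicators, as.data.frame(sim$X))
fit <- gibbs_fit(dat, spec, tau = 0.5, seed = 1, store_latent = 300)
subset(fit$summary, grepl("^gamma_", parameter),
       c(parameter, mean, lower, upper, significant))
#>             parameter  mean lower upper significant
#> 1 gamma_socioeconomic 0.177 0.120 0.238        TRUE
#> 2      gamma_personal 0.789 0.716 0.873        TRUE

residual_sign_fraction(fit)$sign_fraction      # calibration: ~ tau
#> [1] 0.499
```

The two `gamma` rows are the associations of the latent socioeconomic and
personal stressor domains with the median of the latent profile, on the
standardized-indicator scale; both credible intervals exclude zero, and
the personal domain dominates, matching the generating truth
`gamma = (0.2, 0.8)`. The residual sign fraction near `tau` confirms the
quantile calibration of the fit.

The full analysis — simulate, factor construction, all five quantiles,
classical comparison and posterior predictive check — is scripted under
`analysis/` (run `Rscript analysis/01_simulate.R` through
`04_model_checking.R`; tables land in `results/`).

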