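# rayage

Age-and-growth inference for batoids (and other elasmobranchs) aged from
vertebral band pairs. The package implements, as one tested chain, the
analyses a fisheries biologist runs between "a box of sectioned vertebrae"
and "growth parameters usable for assessment":

* **Reading precision** — Beamish–Fournier APE, Chang's CV, percent
  agreement, and a modified age-bias table with per-reference-age
  one-sample t-tests; optional third-read adjudication.
* **Band-deposition periodicity** — maximum-likelihood comparison (AIC) of
  no-cycle, annual (von Mises) and biennial (half-year-offset von Mises
  pair) models for monthly opaque-edge frequencies.
* **Proportionality & back-calculation** — disc width (DW) on vertebral
  radius (VR) regression with ANCOVA sex pooling, then Francis's linear
  body-proportional hypothesis
  `DW_t = DW_c (a + b VR_t) / (a + b VR_c)`.
* **Growth modelling** — Bayesian fits (MCMC via JAGS) of the logistic,
  Gompertz, and two- and three-parameter von Bertalanffy curves with
  zero-truncated priors (`DW∞ ~ N(0,700)`, `k ~ N(0,1)`, `t0 ~ N(0,8)`,
  `σ ~ t(3,0,40)`), R-hat/ESS convergence checks, AIC-at-posterior-means
  model selection with Akaike weights (WAIC alongside), and posterior sex
  contrasts (significant when the 90% credible interval of θ_F − θ_M
  excludes zero).
* **Life history** — Ricker's theoretical longevity `5 ln(2)/k` versus
  observed maximum age, and cross-species comparative statistics (Spearman
  correlations, quadratic k–DW∞ relation) over a bundled table of
  published dasyatid growth parameters.
* **Synthetic truth** — `simulate_population()` generates populations with
  known growth, deposition seasonality, read error and gear selectivity,
  constructed so that back-calculation recovers the true size-at-age
  exactly when noise is off; every stage is validated against it.

## Worked example

```r
library(rayage)

cfg  <- sim_config(n_fish = 272, seed = 1)   # study-scale synthetic population
ds   <- simulate_double_reads(simulate_population(cfg))

precision_report(ds$fish)
#> Ageing precision (n = 272 fish):
#>   APE 3.04%  CV 4.29%  agree 82.7% exact, 100.0% within 1 y

select_edge_model(aggregate_edges(ds$fish))
#> Band-pair deposition periodicity (AIC model comparison):
#>   hypothesis n_params  loglik    aic  delta weight
#> 1   one_peak        3  -93.73 193.45   0.00      1
#> 2   two_peak        3 -143.63 293.26  99.81      0
#> 3  zero_peak        1 -156.63 315.25 121.80      0
#> Best: one_peak

dwvr <- fit_dw_vr(ds$fish)
#> DW-VR regression (n = 272): DW = 164.78 + 102.85 * VR,  r2 = 0.989, ...

pairs <- back_calculate(ds$fish, dwvr)
fit   <- growth_fit(dw ~ age, build_growth_input(pairs, "M"),
                    family = "logistic", chains = 2, warmup = 500,
                    iter = 1000, seed = 1, sex = "M")
fit
#> Bayesian growth fit: logistic (M)
#>   n = 1548 observations; 2 chains x 1000 retained draws
#>          mean    sd    q2.5  ...     q97.5  rhat      ess
#> linf  398.627 1.340 396.088  ...   401.245 1.013  181.114
#> k       0.446 0.008   0.429  ...     0.461 1.004  132.243
#> t0     -0.476 0.028  -0.532  ...    -0.424 1.008  337.513
#> sigma  18.418 0.319  17.800  ...    19.070 1.000 1253.315
#>   AIC (at posterior means) = 13416.60; WAIC = 13416.63
#>   predicted size-at-birth = 220.4 mm; converged: TRUE
```

The agreement statistics say the simulated double reads never disagree by
more than a year; the periodicity table gives all Akaike weight to an
annual deposition cycle (peak in December, as generated); and the growth
fit recovers the generating logistic truth (DW∞ = 401.7 mm, k = 0.45,
t0 = −0.36) within a few posterior SDs, predicting a ~220 mm size at
birth. `longevity_table(coef(fit)[["k"]], 10)` then gives a theoretical
longevity of 7.8 years against the 10-year observed maximum.

`run_pipeline(pipeline_config(...))` chains all stages (precision →
periodicity → regression/ANCOVA → back-calculation → growth fits for both
sexes → comparison → contrasts → longevity → comparative) and can write
the tabular outputs plus a seeded run manifest; `coef`, `summary`,
`predict`, `plot`, `simulate`, `residuals` and `logLik` methods are
available on every `growth_fit`.

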