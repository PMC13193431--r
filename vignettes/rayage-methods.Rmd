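---
title: "Methods: age and growth inference from vertebral band pairs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: age and growth inference from vertebral band pairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(rayage)
```

# The problem

Exploited elasmobranchs are routinely aged by counting band pairs (one
opaque plus one translucent zone) in sectioned vertebral centra. Turning
those counts into growth parameters usable for stock assessment requires a
chain of analyses, each with its own assumptions:

1. **Reading precision** — are repeated counts consistent enough to be
   called ages?
2. **Deposition periodicity** — is one band pair laid down per year, so a
   count is a year?
3. **Structure–soma proportionality** — does the centrum grow in step with
   the body, so interior bands encode earlier sizes?
4. **Back-calculation** — reconstruct size-at-age from interior band radii.
5. **Growth modelling** — fit candidate growth functions and pick one.
6. **Plausibility** — longevity checks and cross-species comparison.

`rayage` implements this chain as testable functions plus a
synthetic-population generator with known truth, so every stage can be
validated against data where the right answer is known.

# Precision statistics

For fish $j$ with $R$ reads $x_{ij}$ and mean $\bar x_j$, the average
percentage error is
$\mathrm{APE} = 100 \cdot \mathrm{mean}_j \big[ \tfrac1R \sum_i |x_{ij}-\bar
x_j| / \bar x_j \big]$ and the coefficient of variation averages the
per-fish relative SD. For $R = 2$, $\mathrm{CV} = \sqrt2\,\mathrm{APE}$
exactly, which the test suite asserts at machine precision. Fish whose
reads average zero are excluded from both denominators (their relative
error is undefined) but still count toward percent agreement. The age-bias
table runs a two-sided one-sample t-test of first-session reads against
each second-session (reference) age; rows with one fish or zero variance
report no p-value rather than a spurious one. When a third read exists,
disagreements between the first two reads are resolved by the third if it
matches either, and the fish is excluded otherwise — the standard
adjudication narrative implemented literally.

# Band-deposition periodicity

Monthly counts of opaque vertebral edges (birthmark-only and unreadable
edges excluded) are modelled as binomial with month-specific probability
$\pi(m)$ under three hypotheses, compared by AIC:

* **zero peak** (no cycle): $\pi = p$, 1 parameter.
* **one peak** (annual cycle): a peak-normalised von Mises bump
  $\pi(m) = A\,e^{\kappa(\cos(\theta_m-\mu)-1)}$, 3 parameters, where
  $\theta_m = 2\pi(m-0.5)/12$ is the mid-month angle. $A \in (0,1]$ is the
  opaque probability in the peak month; $\kappa \ge 0$ the seasonal
  concentration.
* **two peak** (biennial cycle, two band pairs per year): two equal-weight
  von Mises components exactly half a year apart with shared $\kappa$,
  which collapses to the closed form
  $\pi(m) = A\,\cosh(\kappa\cos(\theta_m-\mu_1))/\cosh(\kappa)$,
  3 parameters.

Two design choices deserve comment.

**Peak normalisation.** The original periodicity method's exact link is
not reproduced here; dividing the (mixture) density by its maximum and
scaling by an amplitude keeps $\pi \in [0, A] \subseteq [0,1]$ while
preserving the two features the analysis interprets — peak timing and
seasonal contrast.

**The constrained two-peak form.** A freely parameterised two-component
mixture (two free means, free mixing weight) strictly nests the one-peak
model with two extra boundary parameters. AIC then prefers it whenever its
log-likelihood gain exceeds 2, which happens on roughly a fifth of tables
truly generated from an annual cycle — a structural false-alarm rate that
no amount of data removes. The biennial hypothesis as used in the field
means two band pairs per year, i.e. peaks half a year apart; fixing that
phase (and equal weights) makes the hypothesis scientifically sharp and
the selection experiment well behaved. With this form the no-cycle model
is nested in *both* peaked models (via $\kappa \to 0$, $A = p$), and the
likelihood-ordering property is asserted for exactly those nestings. The
fitter guarantees the orderings by including the nested solution among its
multi-start points (12 peak-location starts for the annual model, 6 for
the biennial, plus the no-cycle solution), refining each by Nelder–Mead
and keeping the best optimum; ties break to the first found.
Probabilities are clamped to $[10^{-9}, 1-10^{-9}]$ inside logs only.

# Proportionality and back-calculation

Disc width is regressed on vertebral radius by ordinary least squares,
$DW = a + b\,VR$. Sexes are pooled when an ANCOVA finds neither a
sex-by-radius interaction (separate slopes) nor a sex intercept effect at
$\alpha = 0.05$ (configurable); the pipeline follows this decision
automatically, with a switch to force per-sex fits.

Size at band age $t$ follows the linear body-proportional hypothesis,
$$DW_t = DW_c\,\frac{a + b\,VR_t}{a + b\,VR_c},$$
with $DW_c, VR_c$ the size and centrum radius at capture. (The formula is
implemented from its cited source; it is scale-equivariant and returns
$DW_c$ exactly at the vertebral edge, both asserted in tests.) Each band,
including the birthmark (age 0), yields one (age, size) pair. Fish with a
non-positive denominator or radii exceeding the centrum radius are skipped
with a warning, never silently.

# Growth modelling

Four families are fitted to the back-calculated pairs:

| family | equation | parameters |
|---|---|---|
| vbgm3 | $DW_\infty(1-e^{-k(t-t_0)})$ | $DW_\infty, k, t_0$ |
| vbgm2 | $DW_\infty-(DW_\infty-DW_0)e^{-kt}$ | $DW_\infty, k$; $DW_0$ fixed |
| gompertz | $DW_\infty e^{-e^{-k(t-t_0)}}$ | $DW_\infty, k, t_0$ |
| logistic | $DW_\infty/(1+e^{-k(t-t_0)})$ | $DW_\infty, k, t_0$ |

plus a residual SD $\sigma$, with i.i.d. Normal errors across
observations. Treating longitudinal back-calculated points as independent
is deliberate: it mirrors how such data are conventionally fitted. The
pseudo-replication it entails (several points per fish) narrows posterior
intervals somewhat and is documented rather than corrected.

Priors are weakly informative on the millimetre scale of medium-sized
batoids: $DW_\infty \sim N(0, 700)$ and $k \sim N(0,1)$ truncated at zero,
$t_0 \sim N(0, 8)$ untruncated (inflection and zero-size ages are
legitimately negative), $\sigma \sim$ Student-t$(3, 0, 40)$ truncated at
zero. `vbgm2`'s $DW_0$ defaults to the mean observed age-0 size in the
input.

Sampling is MCMC via JAGS with fixed per-chain RNG seeds derived from one
integer seed, so fits are exactly reproducible. The default run uses 4
chains, 1000 warm-up iterations discarded and 3000 retained per chain
(12,000 retained draws). Convergence requires $\hat R < 1.10$ for every
parameter, with effective sample sizes (target > 400 per parameter)
reported alongside; failures raise warnings and flag the fit, never pass
silently. A `prior_only` mode samples the prior alone; the test suite
checks its $DW_\infty$ draws against the closed-form truncated-normal
quantiles.

**Model selection.** The primary criterion is a point AIC,
$2p - 2\log L$ at the posterior means ($p$ counts free parameters
including $\sigma$), with Akaike differences and weights; WAIC is computed
from pointwise posterior log-likelihoods as a fully Bayesian diagnostic.
Published AIC values for such fits are often on bespoke scales, so no
numerical reproduction of any published AIC column is attempted — only the
selection *outcome* is testable, and it is tested on synthetic data.
Criteria are refused across non-identical datasets.

**Sex contrasts.** For each parameter shared by the female and male fits
of one family, the posterior difference (females minus males) is formed by
pairing pooled post-warmup draws after an independent seeded shuffle of
each side — the fits are independent, so the pairing affects only
reproducibility. A parameter differs significantly when the equal-tailed
90% credible interval excludes zero; equal-tailed rather than HPD
intervals are used because the contrast distributions are near-symmetric
and equal-tailed bounds are quantile-exact from draws.

**Longevity.** Ricker's theoretical longevity $5\ln(2)/k$ (age at 95% of
$DW_\infty$) is paired with the maximum observed age per sex as a
plausibility check, conventionally using the best-fitting model's $k$.

# The synthetic population

`sim_config()` defaults describe the study conditions the package is
designed around: 272 fish at a 201:71 male:female ratio, sexually
dimorphic logistic growth (males $DW_\infty = 401.7$ mm, $k = 0.45$,
$t_0 = -0.36$; females $512.22$ mm, $0.29$, $0.82$), residual SD 20 mm, a
common linear DW–VR relation ($a = 160$ mm, $b = 105$ mm/mm — chosen so a
~217 mm neonate has a ~0.55 mm birthmark radius and a 465 mm adult a ~2.9
mm centrum, the scale of sectioned dasyatid centra), radius measurement SD
0.05 mm (ImageJ-scale digitisation precision), annual opaque-band
deposition peaking mid-December with von Mises concentration 2 and peak
probability 0.9, a 12.5% one-year read-error rate, monthly sampling May
2022–April 2024, and bell-shaped gillnet-like retention centred at 375 mm
with 75 mm spread. Ages are uniform on 0–11 by default; the observed age
structure of any one fishery is gear-biased, so no empirical age
distribution is baked in. Where the emulated study did not state a value
(the DW–VR coefficients, $\sigma$, the selectivity curve, the age
distribution), the defaults above are the package's own one-time choices
and are labelled synthetic conventions.

Two constructions matter for testability:

* **Noise as persistent individual scale.** The capture-size residual is
  applied as a multiplicative factor to the fish's whole trajectory, and
  interior band radii are placed by inverting the body-proportional
  formula at the true $(a, b)$. Consequently back-calculation recovers
  each fish's true size-at-age exactly (to floating point) when
  measurement noise is off — the identity the pipeline tests lean on — and
  band radii are always strictly inside the centrum radius. A band
  deposited in the capture month sits at the vertebral edge and is clamped
  strictly inside by a relative $10^{-9}$.
* **Stage-keyed RNG streams.** Each stage (population, vertebrae, edges,
  reads) draws from a sub-seed derived from the base seed and a fixed
  label, so adding a stage never shifts another stage's draws.

Within-year growth uses the age fraction
$((\text{capture month} - \text{deposition month}) \bmod 12)/12$: ages are
integers at band deposition but sizes are continuous between depositions.
Capture-induced abortion sizes are not simulated; the smallest sizes come
from the curve.

What the generator does *not* emulate: spatial structure, gear-specific
fleets, multi-species mixtures, correlated reader error, or
individual-level growth heterogeneity beyond the single scale factor.
Passing recovery tests therefore shows the estimators are correct under
the stated model, not that the model captures every feature of real
ageing data.

# Comparative statistics

The packaged cross-species table transcribes published dasyatid growth
parameters (20 rows; two Aegean Sea rows with implausible $k$ and
size-at-birth estimates are flagged and excluded by default, the stated
convention of the source plots). `comparative_stats()` reports the
Spearman correlation (average ranks for ties; t-approximation for
p-values, exact permutation when $n \le 10$) between $k$ and $DW_\infty$
with a least-squares quadratic, and between $DW_0/DW_\infty$ and
$DW_\infty$ with a least-squares line. Under the stated-exclusions row set
the quadratic coefficients reproduce the published curve to four
significant figures and $\rho(k, DW_\infty) = -0.76$; the second
correlation computes to $-0.74$ against a published $-0.75$, and no
row-set convention reproduces both correlations simultaneously. Because
the point set behind such plots is rarely fully specified when studies
print both pooled and sex-specific fits, `comparative_sensitivity()`
recomputes both correlations under the plausible conventions
(stated exclusions only; additionally dropping pooled rows duplicated by
sexed rows from the same study; all rows) so the sensitivity is visible
rather than buried.

# Problem sizes and numerical choices

The test suite fits reduced MCMC runs (2 chains, 300 warm-up, 500–600
retained draws) whose posterior-mean accuracy is ample for the assertions
made, and sizes its simulation experiments as: 200 seasonal plus 100 flat
edge tables (monthly n = 30) for periodicity recovery; single fits at
n = 200 for parameter recovery and truncation; 8 replicate pairs at
n = 200/sex for sex-contrast power; and 50 replicate populations of 272
fish run through regression, back-calculation and all four growth fits
for model recovery. All experiments are seeded and deterministic.

Other numerical conventions: binomial log-likelihoods omit the constant
binomial coefficient (identical across hypotheses, so AIC differences are
unaffected); edge-model angles are wrapped to $[0, 2\pi)$ and the
two-peak mean to $[0, \pi)$ (half-year-apart peaks are exchangeable);
WAIC thins to at most 2000 draws; credible/prediction bands use at most
4000 draws.

# Known limitations

* Back-calculated points are treated as independent; a hierarchical
  (per-fish) error structure would widen intervals.
* The point-AIC criterion is a pragmatic bridge between Bayesian fits and
  the field's AIC habit; WAIC is reported but not used for ranking.
* The ANCOVA operates on the observed radius, so strong measurement error
  in VR can induce sex differences via differential attenuation even when
  the underlying relation is common.
* Theoretical longevity inherits the best model's $k$; it is a
  plausibility check, not an estimator with uncertainty.
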