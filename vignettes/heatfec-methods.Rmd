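---
title: "Models and methods behind heatfec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind heatfec}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heatfec)
```

## The experimental setting

heatfec analyses a repeated-measures reproduction experiment on a
predator–prey pair of mites: a predatory mite (ellipsoid eggs, feeds on
spider-mite eggs) and its spider-mite prey (spherical eggs, feeds on bean
leaf tissue). Females are caged singly on leaf arenas inside programmable
incubators that run one of two diurnal heat-wave regimes — *mild*
(T~max~ = 32 °C) or *extreme* (T~max~ = 38 °C), each a repeating cycle of
twelve 2-hour temperature/humidity blocks under 16:8 h light:dark
(`heatwave_profile()`). Crossed with the adult regime is *acclimation*:
whether juvenile development already happened under the same regime.
Each female is observed once per day for 10 days. Because females eclose
over about a day, the cohort's mean age is 3.5 days at the first
assessment and 12.5 days at the last. Daily records are her state (alive
on the arena, dead, or escaped), eggs laid, and food consumption; up to
two of her eggs per day are measured and reared to adulthood so their sex
becomes known.

## The age-dependent rate model

The package's central model, used for oviposition rate, predation rate
and egg volume, is

$$y(t) = a\,t^{b}\,e^{ct + dt^2},$$

with female age $t$ in days. The model is positive for $t>0$; with
$b > 0$ it passes through zero at eclosion, and with $c < 0$, $d = 0$ it
is the gamma-shaped fecundity curve typical of fast-developing
arthropods: a rise to a single interior peak at $t^* = -b/c$
(`peak_age()`), then decline. Setting $b = 0$ gives the log-quadratic
trend used for egg volumes; $b = d = 0$ gives the exponential decline
used for predation rates. Egg-volume curves are expressed in units of
$10^6\,\mu m^3$, the natural scale of mite egg volumes.

Two fitting routes are provided, mirroring how such data are analysed in
practice:

* **`fit_rate_curve()`** — nonlinear least squares on the natural scale,
  pooling all female-days in a stratum. The optimizer is
  Levenberg–Marquardt (`minpack.lm::nlsLM`, `ftol = 1e-10`) with the
  model written as $\exp(\log a + b\log t + ct + dt^2)$ so the scale
  parameter stays positive; starting values are the back-transformed
  coefficients of a log-linear regression, making fits deterministic.
  $R^2$ is $1 - SSE/SST$ on the response scale. Whether observations
  should instead be weighted per female is not determinable from the
  design alone; pooling is the documented choice.
* **`fit_rate_gee()`** — the log-linearization
  $\ln y = \beta_0 + \beta_1\ln t + \beta_2 t + \beta_3 t^2 + \varepsilon$
  fitted as working-independence estimating equations (ordinary least
  squares on the log scale) with a cluster-robust sandwich covariance
  over females. This reproduces Wald-type between-subject tests for the
  treatment factors without positing an (unknown) within-female
  correlation structure. Factors use sum-to-zero coding, so factor
  effects are multiplicative shifts of $a$ and per-term Wald chi-squares
  are Type-III tests. Backward elimination removes terms with
  $p > 0.05$ stepwise, largest $p$ first, never removing a main effect
  that still appears in a retained interaction.

For oviposition and predation counts, 1 is added before taking
logarithms (daily zeros are common); egg volumes, which are strictly
positive, are logged directly. The `+1` offset means the log-linear mean
model is intentionally *not* an unbiased estimate of the natural-scale
parameters for low counts — it is a device for factor inference. The
package therefore recovers count-curve parameters with
`fit_rate_curve()` and uses `fit_rate_gee()` where the log scale is
exact, i.e. for egg volumes with multiplicative lognormal noise.

## Fates: escape, death, and the Gehan–Breslow test

Escape and death are competing daily fates. `km_curve()` gives the
product-limit (Kaplan–Meier) estimate of $f(t)$, the probability of
still residing on the arena (escape endpoint) or of being alive (death
endpoint), at daily resolution, delegating the estimation to the
survival package. The competing fate censors; for the death endpoint the
default reproduces the convention of conditioning on never-escapers
(`restrict = TRUE`), with plain escape-censoring available as an option.
Ties follow the standard convention: all same-day events share the risk
set of that day, and censoring at a day happens after that day's events.

`breslow_test()` compares groups with the generalized Wilcoxon
(Gehan–Breslow) weighting: each distinct event time contributes its
observed-minus-expected events weighted by the total number at risk, so
differences early in the experiment — when most females are still
present — dominate. The covariance is the conditional hypergeometric
(permutation) form, and the statistic the quadratic form
$U^\top V^{-} U$ on $k-1$ df. Because the chi-square reference is
asymptotic, a permutation $p$ (exact enumeration for small two-group
data, Monte-Carlo otherwise) is available; for two groups the permuted
statistic is $|U_1|$ itself, which the test suite verifies against an
independent pairwise-score implementation (the two formulations agree in
magnitude by the Mantel identity). How exactly legacy software corrects
ties in this test is not documented; the hypergeometric variance is used
because it is exactly checkable against the permutation distribution.

## Ratio-of-means effect summaries

Heat-wave effects on mean daily oviposition are summarized as the ratio
$m = a/b$ of the extreme-regime mean to the mild-regime mean
(`ratio_of_means()`), with the first-order delta-method standard error
$SE(m) = m\sqrt{(SE_a/a)^2 + (SE_b/b)^2}$ for independent groups and a
$t$-based 95 % interval. The approximation is validated in the test
suite against a $10^5$-draw parametric bootstrap and is accurate while
the denominator CV stays below about 0.1. Two ratios are compared with
$t = (m_1-m_2)/\sqrt{SE_1^2+SE_2^2}$ (`compare_ratios()`); the default
df convention is the total of the four group sizes minus 4. (The df
printed in the source experiment cannot be reconstructed exactly from
its group sizes; when reproducing those numbers the package recomputes
the statistic and reports its own df.) `percent_change()` is
$100\,(a-b)/b$.

## Factorial GLMs

Female-level summaries are analysed with `fit_factorial()`: a normal
identity-link model for feeding damage (classical two-way ANOVA), a
log-link quasi-Poisson model for short-horizon egg counts, and a
logit-link quasi-binomial model for per-female offspring sex counts.
For the quasi families the covariance is scaled by the Pearson
$\chi^2/\text{df}$ dispersion, guarding the type-I error against
extra-Poisson/binomial variation — the test suite shows the unscaled
test is anticonservative on overdispersed counts while the scaled one
holds its nominal size. Term tests are Type-III Wald statistics under
sum-to-zero coding; elimination works as in the rate model.

Post-hoc contrasts (`posthoc_contrasts()`) compare a factor's estimated
marginal means on the link scale. For the normal family the exact Tukey
studentized-range adjustment is available; for quasi families the exact
multivariate-$t$ adjustments of legacy software are out of scope, and
pairwise dispersion-scaled Wald $z$ tests with a Holm step-down are used
instead (labelled as analogues). A control-versus-others mode covers
Dunnett-style use. Sex ratios (`sex_ratio_analysis()`) aggregate sexed
eggs per mother over the whole period (not per day) and, like the
feeding and curve analyses, restrict to females that survived the full
period, matching the analysis population of the source design.

## The synthetic cohort generator

`simulate_cohort()` is a first-class, tested individual-based generator
whose defaults (`default_cohort_configs()`) encode the study conditions:
eight cells (species × acclimation × regime) with the published cohort
sizes (42–54 predator, 39–52 prey females), the published oviposition,
predation and per-sex egg-volume curve estimates as generating truths,
per-regime offspring sex ratios, and daily escape/death hazards
calibrated in closed form (`calibrate_hazards()`) so the expected 10-day
fate fractions equal the published per-cell tallies.

Each simulated day proceeds in a fixed order — fate first (escape, then
death), then eggs, then consumption, then the sexing subsample — since
the within-day ordering is not observable in daily records. Egg counts
are negative binomial with variance `count_dispersion × mean`
(default 2, i.e. moderate extra-Poisson variation, reducing to Poisson
at 1), multiplied by a female-level lognormal frailty
(`frailty_sd = 0.2` on the log scale) that induces the within-female
day-to-day correlation the clustered analyses assume; no estimate of
that correlation is available, so the frailty SD is a free, documented
parameter rather than a calibrated one. Egg volumes are lognormal around
the per-sex curve with CV 0.05, consistent with the near-unity $R^2$ of
the published volume fits; predator egg axes are reconstructed from the
volume with a fixed semi-major:semi-minor ratio of 1.3, in the middle of
the range typical for phytoseiid eggs. Prey leaf damage is normal
(SD 4 mm²/day, roughly matching the dispersion implied by the published
standard errors at the published group sizes) truncated at zero.
Females laying on their fate day are not observed, so eggs stop strictly
before `fate_day`.

What the generator deliberately does **not** emulate: instantaneous
within-day temperature dependence (cohorts carry regime labels, not
thermal physiology), spatial behaviour, predation-risk cue treatments
(risk enters only as mean shifts where analysed), and any
acclimation effect on rate curves (none was detectable in the source
experiment, so acclimation alters only cohort sizes and hazards).
Passing recovery tests therefore show that the estimators are correct
under the assumed generative model — not that the model captures every
feature of real mite data (e.g. non-lognormal frailty, age-dependent
hazards, or sex-ratio drift with maternal age).

## Numerical and design choices

* Degenerate inputs are rejected early with named errors: hazards and
  probabilities outside $[0,1]$, all-zero responses, single-age
  (rank-deficient) curve data, empty factor cells (aliasing report),
  zero events in every group.
* `rate_curve_params()` admits $a = 0$ as an explicit null curve so a
  response can be switched off in simulations; fitted scales are always
  positive because the optimizer works on $\log a$.
* A numerically exact GLM fit has zero dispersion; the Wald machinery
  floors it at $10^{-12}$ so the term table stays defined (p-values then
  approach 0), and a saturated fit falls back to dispersion 1.
* Display rounding (one decimal, half-up) is applied only when printing
  regime tables; all computation keeps full precision.
* All randomness flows from explicit integer seeds; simulation output
  and the whole pipeline are bit-reproducible given (inputs, config,
  seed).

## Problem sizes used by the shipped checks

The test suite and the acceptance script size their simulations so the
whole battery runs in a few minutes on one core: 100 replicate cohort
fits of 200 females each for parameter recovery, 1000 null simulations
at 40 females per group for the Breslow type-I error, 5000 females for
the Kaplan–Meier/geometric comparison, $10^5$ draws for the bootstrap
check of the delta-method SE, and 12-female cells for the byte-identity
pipeline runs. These sizes are the package's chosen trade-off between
Monte-Carlo resolution and runtime.

## Known limitations

* The delta-method interval is symmetric; no Fieller interval is
  offered (the bootstrap check justifies the simpler form at the CVs
  seen here, but heavy-noise denominators would need Fieller).
* The Gehan–Breslow asymptotic p is unreliable below ~10 events; use
  `p_method = "permutation"` there.
* `fit_rate_gee()` with the +1 offset targets factor inference, not
  unbiased natural-scale curve recovery for low counts; use
  `fit_rate_curve()` for the latter.
* The quasi-family post-hoc adjustment is Holm, not an exact
  multivariate-$t$; adjusted p-values are mildly conservative.
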