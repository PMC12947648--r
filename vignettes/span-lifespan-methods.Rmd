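---
title: "Methods: joint sleep, activity and diet effects on lifespan and healthspan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: joint sleep, activity and diet effects on lifespan and healthspan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Sleep duration, moderate-to-vigorous physical activity (MVPA) and diet
quality are usually studied one behaviour at a time, which hides both their
joint dose–response structure and any synergy between them.  `spanlife`
implements a complete analysis chain for the joint question: given a cohort
with device-style sleep (h/day), MVPA (min/day) and a 0–100 diet quality
score (DQS), how many years of *lifespan* (period life expectancy) and
*healthspan* (life expectancy free of CVD, cancer, type II diabetes, COPD
and dementia) are associated with combined improvements in the three
behaviours — and what is the smallest combined improvement with a
statistically meaningful gain?

The chain is: exposure cleaning → 27-category joint tertile Cox model and
restricted-cubic-spline dose–response → hazard-ratio-adjusted period life
tables (lifespan) and a disease-free life-table extension (healthspan) →
additive-interaction indices → a composite 0–100 behaviour score whose
increments are inverted back into native behaviour units (minimum-dose
tables).

Because the cohorts this methodology targets are access-restricted, the
package ships a synthetic-cohort generator as first-class, tested code; it
defines the study conditions under which every statistical property of the
pipeline is verified.

## Exposure preparation

* **Winsorisation.** Each exposure is clamped at its 2.5th/97.5th
  percentiles (linear-interpolation percentile definition, R type 7 — the
  bounds depend on this choice, so it is fixed and documented).  A Tukey
  fence alternative (`Q1 − 1.5·IQR`, `Q3 + 1.5·IQR`) is available for
  sensitivity analyses.  Winsorisation preserves the sample size; only the
  tails are replaced.  Note that strict idempotence does not hold under
  interpolated percentiles (re-winsorising shifts the extreme interpolated
  percentiles slightly inward); interior values are exactly stable.
* **Tertiles** are cut at the 1/3 and 2/3 percentiles of the *winsorised*
  values, sexes pooled (a single set of ranges is reported).  Ties at a
  cut go to the lower tertile, deterministically.  The winsorised min/max
  are the endpoints of the reported tertile ranges.
* **Joint categories.** The 3×3×3 grid maps bijectively to indices 1–27
  with diet varying fastest, then MVPA, then sleep; category 1 (all-low)
  is the reference.
* **Exclusions** are applied in a fixed order (data-validity → first-year
  deaths → health-status rules); the order affects only the per-rule
  counts in the log, never the final analytic set.  First-year deaths are
  excluded by default to limit reverse causation.

## Survival models

All-cause mortality (and each condition, where needed) is modelled with a
multivariable Cox proportional-hazards model, Efron tie handling, adjusted
by default for age, sex, smoking, deprivation, alcohol, discretionary
screen time and light-intensity physical activity.  The joint exposure
enters as a 26-indicator block against the all-low reference.  Categories
with zero events are reported as missing rather than as infinite hazard
ratios.  Proportional hazards are checked with Schoenfeld-residual tests
(per term and global) and functional form with martingale-residual
correlations against continuous covariates, flagged at α = 0.05.

Continuous dose–response uses a restricted cubic spline (natural cubic
spline, Harrell parameterisation: linear beyond the boundary knots).  The
default is 4 knots at the 5/35/65/95 percentiles; the count (3–5) and
locations are configurable because no single placement is canonical.  The
curve is centred so the hazard ratio is exactly 1 at the reference value,
by default the exposure's 5th percentile.  Confidence bands use the delta
method on the spline coefficient block.

## Life tables

Lifespan uses a conventional period life table (Chiang construction):
`q = w·m/(1 + 0.5·w·m)` with separation factor `a = 0.5` for all closed
intervals (the cohort starts in mid-adulthood, so no infant-mortality
correction is needed), radix 100,000, open final interval `L = l/m`,
`e = T/l`.  With a single open interval this reduces to `e = 1/m` exactly,
which anchors the tests.  The default start age is 65, the 5-year interval
boundary nearest the emulated cohort's median age (64).

Fitted hazard ratios adjust the age-specific rates uniformly across ages
(`m′ = m·HR`; proportional hazards carried into the life table).  Two
interpretations of the baseline schedule are provided: `none` treats it as
the reference-category schedule, `population` recalibrates by the
prevalence-weighted mean HR so the population average reproduces the
baseline — the methodology literature is not explicit about which is used,
so both are surfaced in configuration.

Years gained are `e(start | HR) − e(start | 1)`.  CI endpoints substitute
the HR confidence bounds through the same (strictly monotone) map, which
guarantees interval ordering; this endpoint-substitution convention is a
deliberate, simple-to-reproduce choice rather than a delta-method
approximation.

**Baseline rates.** The packaged mortality and disease-rate tables are
*synthetic* national-style schedules (Gompertz-type mortality,
exponentially rising incidence, logistic prevalence) in the realistic
range for a high-income population (e.g. `e(65) ≈ 21.5` years); real
national tables can be supplied by path in the same CSV dialect.

## Healthspan (disease-free life expectancy)

The disease-free state is exited by the first of death or first incidence
of any of the five conditions, so the exit rate per age interval is
`HR_mort·m + Σ_c HR_c·i_c`.  Baseline prevalence enters through the
starting radix, scaled by `1 − prevalence_any` (independence across
conditions is assumed when combining prevalences); a Sullivan-style mode
that weights every interval's person-years by its age-specific disease-free
proportion is provided as an alternative, since the exact construction in
the source methodology is not derivable from its main text.  With zero
incidence and prevalence, the healthspan table reproduces the lifespan
table to machine precision — a tested reduction property.

Uncertainty uses parametric Monte Carlo (default 10,000 iterations,
seeded): incidence rates are sampled normally on the log scale
(sd = se/rate), prevalences normally on the logit scale
(sd = se/(p(1−p))) — both keep samples in their valid ranges — and,
optionally (default on, switchable), the log hazard ratio from its fitted
normal.  The point estimate is the gain at central values; the 95% CI is
the 2.5/97.5 percentile of the iteration distribution.  Note that the
percentile CI converges to a fixed width as iterations grow; it is the
Monte-Carlo *standard error* of the estimate (reported as `mc_se`) that
shrinks as 1/√iterations, and that is what the tests check.

## Synergy

Additive interaction across the three behaviours uses the joint
three-exposure form against the all-unfavourable reference (favourable =
top two tertiles by default; the dichotomisation is a declared default,
not an asserted convention):

* `RERI = HR₁₁₁ − HR₁₀₀ − HR₀₁₀ − HR₀₀₁ + 2` (0 under additivity),
* `AP = RERI / HR₁₁₁`,
* `S = (HR₁₁₁ − 1) / Σ(HR_single − 1)` (1 under additivity; reported
  missing with a reason when the denominator is 0).

With the protective orientation (reference = least favourable), a positive
RERI means super-additive benefit and negative values a sub-additive
(antagonistic) relationship.  Confidence intervals use the nonparametric
percentile bootstrap over participants (default B = 2,000; BCa was
deliberately not used — the percentile interval is the simplest
reproducible convention).  Resamples with empty states or non-convergent
fits are dropped and counted; more than 20% dropped aborts with advice to
increase n.

## The composite score and minimum doses

Each behaviour contributes a piecewise-linear subscore on [0, 100/3]
(the standardisation function is not recoverable from the source
methodology's main text; piecewise-linear is transparent and exactly
invertible, which the minimum-dose inversion requires):

* sleep — U-shaped, maximal at the 7.5 h/day mortality nadir, 0 at the
  winsorised extremes;
* MVPA — saturating, linear from the winsorised floor to the 50 min/day
  optimum (configurable), flat beyond;
* DQS — monotone linear from the winsorised floor to the winsorised
  maximum.

The composite score is the sum (nominal equal weighting; endpoints exact:
all-optimal = 100, all-floor = 0).  For allocating a *score increment*
across behaviours, model-derived weights are used instead: each
behaviour's marginal log-HR span (mean |log HR high − low| across the
other two behaviours' tertiles in the 27-category model), normalised to
sum to 1.  This reconciles the nominally equal-weighted score with
model-informed increments; both weighting modes are available.

`invert_score_increment()` allocates `Δscore·w_b` subscore points to each
behaviour, capped at its headroom above the reference (the 5th-percentile
exposure values), reallocating any overflow proportionally and logging it;
inverting each piecewise-linear mapping gives increments in native units
(min/day of sleep and MVPA, DQS points).  The round-trip
`score(reference + increments) − score(reference) = Δscore` holds to 1e-6
and is tested over random weights and increments.

The minimum-dose table searches the gain curve on a 0.5-point score grid
(finer than any reported increment): the first row is the smallest score
whose years-gained CI excludes zero; subsequent rows give the smallest
score achieving each whole-year target, decomposed into combined
increments, with single-behaviour equivalents solved on each behaviour's
own dose–response curve and reported missing (with the reason) when a
target is unreachable in isolation.

## The synthetic cohort generator

The generator is a declared stand-in: the emulated study is observational
and publishes no generative model, so all distributional choices are
explicit package decisions.

* **Marginals** (Gaussian copula with configurable correlations): sleep
  Normal(7.5, 1.1) h/day; MVPA logNormal(3.1, 0.75) min/day (median ≈ 22);
  DQS Normal(52.5, 10.2) clipped to [0, 100].  These bracket the reported
  winsorisation bounds and tertile ranges of the emulated cohort; a
  two-parameter marginal cannot reproduce every printed endpoint of the
  real (skewed) distributions, and no attempt is made to.
* **Outcomes**: exponential (constant-hazard) event times with log-hazard
  = baseline + quadratic sleep deviation from a 7.5 h nadir (U-shape)
  + piecewise-linear MVPA flat beyond a 50 min/day knot (inverted J)
  + linear DQS + covariate terms; age enters as a covariate on a
  time-on-study scale (the simpler oracle math; an age time scale was
  deliberately not used).  The five conditions are independent
  proportional-hazards processes given covariates; dependence between
  conditions is out of scope.  Administrative censoring at 8.1 years with
  optional uniform dropout.
* **Defaults** reproduce the emulated study's scale: n = 59,078 and
  baseline rates chosen so expected event counts are near the reported
  ones (≈2,460 deaths; ≈10,000 CVD down to ≈500 dementia first events).

What passing tests on these cohorts show: the pipeline recovers known
hazard structures, nadirs and additive-interaction truths at realistic
sample sizes, with calibrated CIs.  What they do not show: robustness to
the messiness of real cohorts — measurement error, informative censoring,
correlated disease processes, non-proportional hazards — which the
generator deliberately does not emulate.

## Numerical conventions and degenerate inputs

* Percentiles/quartiles: linear interpolation (type 7) everywhere.
* Ties at tertile cuts go low; massive ties spanning a cut warn.
* Life table: `q` clamped to 1 (tables remain valid outside the
  `w·m < 2` regime, though the mid-interval approximation is meant for
  `q < 1`); `m = 0` in the open interval is an error (infinite
  expectancy).
* Zero-event joint categories: missing HRs, never ±∞.
* S index: missing with a recorded reason when its denominator is 0.
* All randomness is seeded; the pipeline derives one deterministic
  substream per stage from the global seed, so toggling a stage never
  perturbs another stage's draws.

## Problem sizes used in the tests

The test-suite simulations use cohort sizes of 1,000–20,000, 200
replicates for CI-coverage studies, B = 200–500 bootstrap resamples and
500–10,000 Monte Carlo iterations; these sizes give stable checks of the
properties above while keeping the default test run quick.  The heavier
published-scale settings (n ≈ 59,000, B = 2,000, 10,000 MC iterations) are
the package defaults for real runs.

## Known limitations

* The healthspan construction treats condition prevalences as independent
  when combining them and allows no return from the diseased state.
* HRs are applied uniformly across ages in the life table (no age-varying
  effects).
* Percentile bootstrap and CI-endpoint substitution are simple,
  reproducible conventions; they do not correct for skewness the way BCa
  or delta-method intervals might.
* The composite-score subscores are piecewise-linear by design; smooth
  alternatives would change minimum-dose decompositions slightly.
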