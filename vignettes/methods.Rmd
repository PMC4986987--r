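---
title: "Methods: predictive risk algorithms for behavioural mortality burden"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: predictive risk algorithms for behavioural mortality burden}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mortburden)
```

# The estimation problem

`mortburden` implements the multivariable predictive approach to measuring
the mortality burden of unhealthy behaviours. Instead of attributing
aggregate death counts to risk factors through externally estimated relative
risks, the approach (i) derives a sex-specific all-cause mortality risk
algorithm from a population health survey linked to death records, (ii)
validates and, where needed, recalibrates it, and (iii) applies it to an
*unlinked* survey, predicting an absolute death risk for every respondent.
Counterfactual burden then falls out of re-predicting risk after recoding
behaviours to their recommended ("healthy reference") levels: attributable
deaths are the weighted difference in predicted annual deaths, and life
expectancy lost is the difference between period life tables built on the
two risk sets.

Because the surveys such algorithms are derived from are typically
restricted-access, the package ships a synthetic survey generator with a
known ground truth. All of the package's claims about correctness are made
against that truth, in closed form wherever possible.

# Exposure coding

Raw survey answers are coded deterministically (`code_exposures()`):

* **Smoking** — five classes: heavy (current, 20+ cigarettes/day, i.e. at
  least a pack), light (current, under a pack), former heavy / former light
  (same pack threshold applied to the amount smoked), and non-smoker
  (never-smoker, or former occasional smoker with fewer than 100 lifetime
  cigarettes). Former smokers carry a continuous years-since-quit term.
  Current occasional smokers with no daily amount are coded light.
* **Alcohol** — heavy if *any* of: more than 21 (men) / 14 (women) drinks in
  the previous week, 5+ drinks on any single day of that week, or weekly
  bingeing; moderate for 4–21 (men) / 3–14 (women) drinks/week; otherwise
  light/non. The single-day and weekly-binge conditions are implemented as
  distinct OR-conditions.
* **Physical activity** — daily averaged MET from the previous month's
  leisure activities: `sum(met * times_per_month * minutes/60) / 30`. A
  precomputed `mets_per_day` column bypasses this.
* **Diet** — a 0–10 score: 2 baseline points, +1 per daily fruit/vegetable
  frequency (juice excluded, capped at 8), −2 for high potato intake (7+/wk
  men, 5+/wk women), −2 for no carrot intake, and −2 per daily juice
  frequency above once/day (floored at −10, applied linearly); negative
  totals are recoded to 0.
* **Neighbourhood deprivation** — material × social quintiles: both in
  {1,2} is low (4 cells), both in {4,5} is high (4 cells), the remaining 17
  cells moderate.

Records missing any model field are excluded (complete-case rule) and
logged with a reason; no imputation is attempted.

# The hazard model

Mortality is modelled with a sex-specific Cox proportional-hazards model.
We use **age as the time scale**: a respondent surveyed at age $a_0$ and
followed for $t$ years enters the risk set at $a_0$ (left truncation) and
exits at $a_0 + t$. The entire age effect — including its steep non-linear
rise — is then absorbed nonparametrically by the baseline hazard, which is
both simpler and more flexible than spline covariates for age combined with
step-updated time-dependent age. This is the package's resolution of a
genuinely open design choice; age–behaviour interactions remain available
as $(a_0 - 50) \times \text{behaviour}$ covariate terms, and ties use the
Efron approximation.

The extracted algorithm (`extract_algorithm()`) is self-contained: the
coefficient vector $\beta$ and covariance, the baseline cumulative hazard
$H_0$ at the reference covariate pattern on an integer age grid (20–105),
and a per-age-bin calibration table. Risk over a horizon $h$ from age $a$ is

$$ q(a, h) = \alpha_{\text{bin}(a)}\left[1 -
   \exp\{-e^{x'\beta}\,(H_0(a+h) - H_0(a))\}\right], $$

clamped to $[0,1]$, with $H_0$ interpolated linearly between grid ages. The
cumulative hazard rather than $S_0 = e^{-H_0}$ is the stored primitive
because $S_0$ underflows to zero at old ages in small fits while $H_0$
stays finite; where $H_0(a+h) = H_0(a)$ the risk is defined as exactly zero
regardless of the hazard ratio.

Covariate groups beyond age and the four behaviours (deprivation,
education, immigration, chronic diseases, BMI class) can be admitted by the
prespecified calibration criterion (`criterion_driven_inclusion()`): a
candidate is added only if omitting it leaves some subgroup holding more
than 5% of deaths with a predicted–observed gap above 20%. Multicollinearity
is reported as variance-inflation factors (flag above 10). A sensitivity
refit excluding the first two years of follow-up guards against a healthy
respondent effect.

# Validation

Discrimination is summarised by the concordance index and the 90:10 risk
percentile ratio. `concordance_index()` supports left-truncated data (a
pair is comparable at a death age only if the comparator was under
observation at that age). For the headline report, `validate_algorithm()`
computes concordance on the follow-up time scale, where age differences
contribute to discrimination — this is how C-statistics for such algorithms
are conventionally reported, and it is why the same model shows C near 0.89
on the follow-up scale but nearer 0.70 on the age-matched scale.
Calibration is assessed as observed versus predicted deaths within a
horizon, by user-defined subgroups and by risk decile; observed deaths are
counted among respondents whose horizon outcome is fully observed (death
within the horizon or at least that much potential follow-up), a simpler
rule than inverse-censoring weighting that is exact under purely
administrative censoring.

# Recalibration

Before burden estimation the algorithm is recalibrated to an external
observed age–sex mortality-rate table: the factor for each bin becomes
$O/P$, where $P$ is the survey-weighted mean *uncalibrated* predicted annual
risk. After this step the weighted predicted bin rates equal the observed
rates to machine precision (unless an individual calibrated risk hits the
$[0,1]$ clamp, which the warnings surface), and recalibrating twice changes
nothing. The factor multiplies annual risk, not hazard — a deliberate
simplification, recorded here because either convention is defensible.
Calibration bins default to the life table's 5-year age groups, which makes
the downstream life expectancy equal the life expectancy implied by the
observed rates themselves.

# Life tables

Life expectancy uses survey-weighted sex-specific abridged period life
tables on the sixteen intervals $[20,25), \ldots, [95,100)$. The interval
death probability is $q = 1 - (1-\bar q)^5$ with $\bar q$ the weighted mean
predicted annual risk of respondents aged in the interval — i.e. annual
risk is treated as constant within the interval, a documented
approximation. Intervals with no respondents are filled by log-linear
interpolation over interval midpoints (log-linear extrapolation at the
edges) and flagged. The standard construction uses a radix of 100,000 and
$a = 2.5$ years lived on average by interval decedents — applied to every
interval including the terminal one, which is closed with $q = 1$ (no
open-ended extrapolation beyond age 100). Life expectancy is reported on
the full lifespan scale ($20 + e_{20}$). The variance of $e_{20}$ follows
the classical delta-method propagation of interval $\mathrm{Var}(q)$
(Chiang's method); the terminal interval, with $q$ fixed at 1, contributes
none. Sexes are reported separately; any combined figure a user forms by
weighted averaging is their own, non-canonical, choice.

# Counterfactual burden

`healthy_reference()` recodes only the requested behaviours: everyone
becomes a non-smoker (former smokers also have the time-since-quit credit
zeroed), heavy drinkers become light/non, METs/day rises to 3 where lower,
and the diet score rises to 8 where lower. Sociodemographics, chronic
diseases and BMI are held fixed — so attribution runs through the full
model, and effects mediated by, say, diabetes are deliberately not credited
to behaviour; this matches full-model attribution and is the acknowledged
direction of possible under-estimate. Attributable deaths use a one-year
horizon with calibrated risks; life expectancy lost uses the life tables
above. One consequence worth knowing: because long-quit former smokers can
have a fitted risk *below* never-smokers, the smoking counterfactual can
raise an individual's risk even though aggregate burden stays positive; the
guarantee "counterfactual risk ≤ baseline risk" holds when every deleted
coefficient points in the unhealthy direction.

Equity breakdowns (`equity_table()`) repeat the whole computation within
levels of education, deprivation, smoking class, and so on; groups smaller
than 50 are flagged. Profile life expectancies use either survey subsets
(healthy: non-smoking, not heavy-drinking, ≥3 METs/day, diet ≥8; unhealthy:
heavy smoking, heavy drinking, <1.5 METs/day, diet <2) or a fixed covariate
vector evaluated at interval midpoints.

# Uncertainty

`bootstrap_burden()` combines two sources per replicate: coefficients drawn
multivariate-normal at the estimates with the fitted covariance, and a
with-replacement respondent resample (within sex, weights rescaled to
preserve the represented population). When an observed rate table is
supplied, every replicate is recalibrated against it, so calibration
interacts with both sources exactly as in the point estimate. Intervals are
percentile (life expectancy lost can be skewed), with the point estimate
included in the replicate pool so it always lies inside its own interval.
The exact design-based survey bootstrap used with restricted survey files
(mean bootstrap weights carrying the design information) requires design
variables we do not have; the scheme above is a stated stand-in, and a
user-supplied replicate-weight hook is a natural extension.

# The synthetic generator

`cohort_config()` defines the study conditions: sex-specific category
prevalences matching a national application survey (for men: heavy smokers
8.2%, light 16.4%, former heavy 14.7%, former light 16.0%; heavy drinkers
20.3%; medians 1.6 METs/day and 3.3 fruit/vegetable servings/day — and the
corresponding figures for women), log-normal survey weights normalized to
12.4M men and 12.9M women, and a Gompertz baseline hazard on the age scale.
The Gompertz parameters (rate 1.5e-4 / 1.2e-4 per year at age 20 for
men/women at the reference pattern, log-slope 0.105 per year — mortality
doubling roughly every 6.6 years) were chosen once so that unweighted crude
death rates land near 100–130 per 10,000 person-years, the scale seen in
derivation cohorts of this kind; they imply baseline life expectancies of
about 77 (men) and 80 (women) years. True log hazard ratios default to the
magnitudes such algorithms report (heavy smoking HR 2.8, protective
continuous effects for METs and diet), and a single latent-propensity
parameter (`latent_rho`, default 0.3) correlates unhealthy behaviours with
low education and deprivation so equity analyses have signal. Ground truth
is available in closed form: `exact_risk()` gives each respondent's true
annual death probability and `true_burden()` the exact counterfactual
burden, which is what parameter-recovery and coverage tests compare
against.

What the generator does **not** emulate: the stratified multistage cluster
design of real surveys (weights are i.i.d. log-normal), nonresponse,
measurement error and under-reporting (notably of alcohol), age-dependent
disease prevalence, and calendar-period trends. Passing tests therefore
demonstrate the estimation machinery is correct under known conditions, not
that any real-data estimate is unbiased against these unmodelled features.

# Numerical choices and problem sizes

Follow-up of exactly zero is lifted to one day so entry precedes exit.
Risks are clamped to $[0,1]$ after calibration. Empty rate-table bins leave
calibration factors unchanged with a warning. The test suite exercises: a
20,000-respondent shared fixture for module tests; a 50,000-respondent
cohort for parameter and burden recovery (behavioural log hazard ratios
within 3 standard errors of truth; the attributable fraction's bootstrap
interval covering the exact counterfactual); and 100 seeded replicates of a
4,000-respondent survey with a 100-draw bootstrap for interval coverage of
life expectancy lost (nominal 95%, required ≥88/100). Brute-force pair
enumeration, closed-form truncated-exponential life tables, and
finite-difference derivatives serve as independent oracles; the `survival`
package's concordance is used as a cross-check only, never as the
implementation.

# Known limitations

Interval death probabilities inherit the constant-annual-risk-within-
interval approximation; the $a = 2.5$ convention is coarse for the terminal
interval; attribution with mediators held fixed understates behaviours'
total effect; the bootstrap omits baseline-hazard estimation error (largely
neutralised when recalibration to an external rate table is in the
pipeline, which is the recommended use); and the concordance bootstrap is
over respondents, not over the survey design.
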