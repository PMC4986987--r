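# mortburden

Estimate the mortality burden of unhealthy behaviours — smoking, alcohol,
physical inactivity, and poor diet — with a **multivariable predictive
approach**: derive a sex-specific all-cause mortality risk algorithm from a
population health survey linked to death records, validate and recalibrate
it, apply it to an unlinked survey, and convert per-respondent predicted
risks into period life tables, counterfactual ("behaviour-deleted") life
expectancy, attributable deaths, and equity breakdowns, with bootstrap
uncertainty.

It is written for epidemiologists and health-planning analysts who have
respondent-level survey data (or want to study the method itself: a seeded
synthetic survey generator with known ground-truth hazards is a first-class
part of the package).

## The model

Death hazard is modelled per sex with a Cox proportional-hazards model on
the **age time scale** (entry at survey age, left truncation; the baseline
hazard absorbs the age effect). The extracted risk algorithm predicts the
probability of death within *h* years from age *a* as

    q(a, h) = alpha_bin(a) * [ 1 - exp{ -exp(x'beta) (H0(a+h) - H0(a)) } ]

where `x` holds coded exposures (five smoking classes with continuous time
since quitting, three drinking categories with a binge rule, METs/day, a
0–10 diet score, deprivation, education, immigration, chronic conditions,
BMI class), `H0` is the baseline cumulative hazard on an integer age grid,
and `alpha` are age–sex calibration factors set from an external observed
mortality-rate table (`alpha = O/P` per bin, after which predicted bin
rates equal observed rates exactly).

Annual predicted risks feed survey-weighted abridged period life tables
(ages 20–99, Chiang construction with delta-method variance for life
expectancy). Burden is the difference between baseline predictions and
predictions after recoding behaviours to recommended levels (non-smoker;
not a heavy drinker; ≥3 METs/day; diet score ≥8).

## Worked example

```r
library(mortburden)

cfg    <- cohort_config(n = 30000, seed = 42)      # synthetic study conditions
cohort <- simulate_followup(generate_cohort(cfg), cfg)
coded  <- code_exposures(cohort)                   # complete-case exposure coding

fit <- fit_hazard_model(coded, model_spec("male"))
round(exp(fit$coef[c("smoking_heavy", "smoking_light", "alcohol_heavy",
                     "mets_per_day", "diet_score")]), 2)
#> smoking_heavy smoking_light alcohol_heavy  mets_per_day    diet_score
#>          2.58          1.95          1.27          0.90          0.97
```

Heavy smoking carries a fitted hazard ratio of 2.58 (true generating value
2.8, within sampling error at ~940 male deaths); each MET/day multiplies
the hazard by 0.90, each diet point by 0.97.

```r
alg <- extract_algorithm(fit)
val <- validate_algorithm(coded, alg, ci_boot = 0)
round(val$c_statistic, 3)
#> [1] 0.889
```

The algorithm discriminates well (follow-up-scale C-statistic 0.889).
Recalibrate both sex algorithms to an observed age–sex rate table and
estimate the combined four-behaviour burden:

```r
obs  <- observed_rate_table(cfg, n = 100000)   # "observed" rates from the truth
algs <- list(male   = recalibrate(alg, coded, obs),
             female = recalibrate(extract_algorithm(
                        fit_hazard_model(coded, model_spec("female"))),
                        coded, obs))
burden_estimate(algs, coded)[, c("baseline_le", "reference_le", "le_lost",
                                 "attributable_fraction")]
#>   baseline_le reference_le le_lost attributable_fraction
#> 1       77.11       82.342   5.232                 0.412
#> 2       80.48       85.607   5.127                 0.433
```

Row 1 is men, row 2 women: deleting all four behaviours would raise male
period life expectancy from 77.1 to 82.3 years (5.2 years lost to
behaviour) and 41% of predicted annual deaths are attributable to the four
behaviours. The generator's exact counterfactual (`true_burden(cfg)`) gives
6.6 years and 50% for men at this configuration — the estimate's bootstrap
interval (`bootstrap_burden()`) covers it at larger derivation sizes, which
is what the test suite verifies.

`equity_table(algs, coded, "education", behaviours = "smoking")` reproduces
the equity view: smoking-attributable life-expectancy loss by education
level, largest where smoking concentrates.

A thin command-line wrapper over these functions is installed at
`inst/cli/mortburden.R` (subcommands `simulate`, `fit`, `validate`,
`calibrate`, `burden`, `run`).

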