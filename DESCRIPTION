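Package: mortburden
Title: Behavioural Mortality Burden via Multivariable Predictive Risk Algorithms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derive, validate, recalibrate, and apply sex-specific all-cause
    mortality risk algorithms from population health survey data, and compute
    the mortality burden of unhealthy behaviours (smoking, alcohol, physical
    inactivity, and poor diet). Exposure coding follows published survey
    definitions (heavy/light smoking with time since quitting, drinking
    categories with a binge rule, leisure-time METs per day, a 0-10 diet score,
    and a two-axis neighbourhood deprivation index). Risk algorithms are
    proportional-hazards models on the age time scale; predicted annual risks
    feed survey-weighted abridged period life tables (Chiang construction with
    delta-method variance), counterfactual healthy-reference recoding,
    attributable deaths and life-expectancy lost, equity breakdowns, and a
    two-source bootstrap for uncertainty. A seeded synthetic survey generator
    with known ground-truth hazards supports end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    survival,
    MASS,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
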