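# Shared simulated-cohort fixtures, built once per test run.
.fixtures <- new.env()

fixture_config <- function() {
  if (is.null(.fixtures$cfg)) .fixtures$cfg <- cohort_config(n = 20000, seed = 202)
  .fixtures$cfg
}

# linked cohort (follow-up simulated under the generator's truth), coded
fixture_coded <- function() {
  if (is.null(.fixtures$coded)) {
    cfg <- fixture_config()
    .fixtures$coded <- code_exposures(simulate_followup(generate_cohort(cfg), cfg))
  }
  .fixtures$coded
}

# sex-specific algorithms fitted on the fixture cohort
fixture_algorithms <- function() {
  if (is.null(.fixtures$algs)) {
    coded <- fixture_coded()
    .fixtures$algs <- list(
      male = extract_algorithm(fit_hazard_model(coded, model_spec("male"))),
      female = extract_algorithm(fit_hazard_model(coded, model_spec("female"))))
  }
  .fixtures$algs
}

# observed age-sex rate table from the generator's truth
fixture_observed <- function() {
  if (is.null(.fixtures$obs))
    .fixtures$obs <- observed_rate_table(fixture_config(), n = 100000)
  .fixtures$obs
}

# a complete single respondent row, overridable field by field
make_respondent <- function(...) {
  r <- data.frame(
    id = 1, sex = "male", age = 50, smoking_status = "never",
    cigs_per_day = NA_real_, lifetime_cigs_lt_100 = TRUE,
    years_since_quit = NA_real_, drinks_last_week = 2,
    max_drinks_any_day_last_week = 1, weekly_binge = FALSE,
    mets_per_day = 2, fruit_veg_freq_per_day = 4, juice_freq_per_day = 0.5,
    potato_freq_per_week = 2, carrot_freq_per_week = 2,
    material_quintile = 3, social_quintile = 3, education = "post_sec",
    years_since_immigration = "gt45_or_born", heart_disease = FALSE,
    stroke = FALSE, cancer = FALSE, diabetes = FALSE, bmi_ge_35 = FALSE,
    weight = 1, stringsAsFactors = FALSE)
  args <- list(...)
  for (nm in names(args)) r[[nm]] <- args[[nm]]
  r
}

# hand-built constant-hazard risk algorithm: baseline hazard `lambda` per
# year at the reference pattern, smoking group only
constant_hazard_algorithm <- function(sex = "male", lambda = 0.01,
                                      heavy_log_hr = 0) {
  grid <- 20:105
  spec <- model_spec(sex, factors = "smoking")
  coef <- setNames(rep(0, 5), c("smoking_former_light", "smoking_former_heavy",
                                "smoking_light", "smoking_heavy",
                                "time_since_quit"))
  coef["smoking_heavy"] <- heavy_log_hr
  cal <- age_bins_5y(); cal$factor <- 1
  structure(list(sex = sex, coef = coef, vcov = diag(1e-8, 5), spec = spec,
                 baseline_age = grid,
                 baseline_cumhaz = lambda * (grid - 20),
                 baseline_s0 = exp(-lambda * (grid - 20)),
                 calibration = cal, n = 0, deaths = 0),
            class = "risk_algorithm")
}
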