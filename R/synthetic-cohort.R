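#' Configuration for the synthetic survey-cohort generator
#'
#' Defines the study conditions the generator emulates: sex-specific exposure
#' prevalences matching a national application survey (heavy smoking around
#' 8.2% of men and 4.0% of women, heavy drinking 20.3%/7.3%, and so on),
#' a Gompertz baseline hazard on the age scale with mortality doubling about
#' every 7.5 years, ground-truth log hazard ratios of the magnitude seen in
#' population mortality algorithms (heavy-smoking hazard ratio 2.8),
#' log-normal survey weights normalized to a represented population, and a
#' shared latent propensity that correlates unhealthy behaviours with low
#' education and neighbourhood deprivation.
#'
#' @param n number of respondents.
#' @param seed integer seed; all generator randomness flows from it.
#' @param sex_split proportion male.
#' @param horizon administrative censoring horizon in years of follow-up.
#' @param latent_rho correlation between the shared unhealthy-propensity
#'   latent variable and each behaviour/sociodemographic draw (0 = all
#'   factors independent).
#' @param weight_sdlog log-scale standard deviation of survey weights.
#' @param pop_total represented population per sex (weights are normalized to
#'   these totals).
#' @param baseline list with `rate20` (named per-sex baseline hazard at age 20
#'   for the reference covariate pattern, per year) and `slope` (Gompertz
#'   log-slope per year of age).
#' @param true_log_hr named vector of ground-truth log hazard ratios, one per
#'   design-matrix column of the full model (see [exposure_design()]).
#' @param prevalences per-sex distributional parameters for the raw survey
#'   fields; see `default_prevalences()` in the package source.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n = 10000, seed = 1, sex_split = 0.49,
                          horizon = 5, latent_rho = 0.3, weight_sdlog = 0.5,
                          pop_total = c(male = 12.4e6, female = 12.9e6),
                          baseline = list(
                            rate20 = c(male = 1.5e-4, female = 1.2e-4),
                            slope = 0.105),
                          true_log_hr = default_true_log_hr(),
                          prevalences = default_prevalences()) {
  stopifnot(n > 0, horizon > 0, sex_split >= 0, sex_split <= 1,
            all(baseline$rate20 > 0), baseline$slope > 0)
  for (s in c("male", "female")) {
    p <- prevalences[[s]]
    for (f in c("smoking", "alcohol", "education", "immigration")) {
      if (abs(sum(p[[f]]) - 1) > 1e-8)
        stop("prevalences for ", f, " (", s, ") must sum to 1")
      if (any(p[[f]] < 0)) stop("negative prevalence for ", f, " (", s, ")")
    }
  }
  structure(list(n = n, seed = seed, sex_split = sex_split, horizon = horizon,
                 latent_rho = latent_rho, weight_sdlog = weight_sdlog,
                 pop_total = pop_total, baseline = baseline,
                 true_log_hr = true_log_hr, prevalences = prevalences),
            class = "cohort_config")
}

#' @rdname cohort_config
#' @export
default_true_log_hr <- function() {
  c(smoking_former_light = log(1.3), smoking_former_heavy = log(1.6),
    smoking_light = log(2.0), smoking_heavy = log(2.8),
    time_since_quit = -0.025,
    alcohol_moderate = log(0.9), alcohol_heavy = log(1.4),
    mets_per_day = -0.12, diet_score = -0.05,
    deprivation_low = log(0.85), deprivation_high = log(1.25),
    education_hs_grad = log(1.15), education_lt_hs = log(1.35),
    immigration_0_15 = log(0.7), immigration_16_30 = log(0.8),
    immigration_31_45 = log(0.9),
    heart_disease = log(1.8), stroke = log(1.7), cancer = log(2.2),
    diabetes = log(1.7), bmi_ge_35 = log(1.4))
}

#' @rdname cohort_config
#' @export
default_prevalences <- function() {
  list(
    male = list(
      smoking = c(non = 0.447, former_light = 0.160, former_heavy = 0.147,
                  light = 0.164, heavy = 0.082),
      alcohol = c(light_non = 0.574, moderate = 0.223, heavy = 0.203),
      education = c(post_sec = 0.629, hs_grad = 0.233, lt_hs = 0.138),
      immigration = c(gt45_or_born = 0.789, "0_15" = 0.094, "16_30" = 0.067,
                      "31_45" = 0.050),
      disease = c(heart_disease = 0.061, stroke = 0.010, cancer = 0.022,
                  diabetes = 0.080),
      bmi_ge_35 = 0.047,
      mets_meanlog = log(1.6), mets_sdlog = 1.25,
      fv_shape = 2.2, fv_scale = 1.77, juice_rate = 1.86,
      potato_shape = 2, potato_scale = 1.9, carrot_p0 = 0.109,
      age_shape1 = 1.5, age_shape2 = 2.8
    ),
    female = list(
      smoking = c(non = 0.561, former_light = 0.176, former_heavy = 0.076,
                  light = 0.147, heavy = 0.040),
      alcohol = c(light_non = 0.724, moderate = 0.203, heavy = 0.073),
      education = c(post_sec = 0.616, hs_grad = 0.242, lt_hs = 0.142),
      immigration = c(gt45_or_born = 0.792, "0_15" = 0.099, "16_30" = 0.062,
                      "31_45" = 0.047),
      disease = c(heart_disease = 0.044, stroke = 0.011, cancer = 0.020,
                  diabetes = 0.058),
      bmi_ge_35 = 0.056,
      mets_meanlog = log(1.3), mets_sdlog = 1.25,
      fv_shape = 2.2, fv_scale = 2.25, juice_rate = 2.15,
      potato_shape = 2, potato_scale = 1.3, carrot_p0 = 0.086,
      age_shape1 = 1.5, age_shape2 = 2.8
    )
  )
}

# uniform draw correlated with latent unhealthy propensity z
correlated_uniform <- function(z, rho) {
  stats::pnorm(rho * z + sqrt(1 - rho^2) * stats::rnorm(length(z)))
}

# ordered categorical draw from a uniform, categories ordered healthy-first
cut_categories <- function(u, probs) {
  names(probs)[findInterval(u, cumsum(probs)[-length(probs)]) + 1L]
}

#' Generate a synthetic survey cohort
#'
#' Draws `config$n` respondents in the raw survey schema (no follow-up):
#' demographics, raw smoking/alcohol/activity/diet answers, deprivation
#' quintiles, sociodemographics, chronic-condition flags, and normalized
#' survey weights. Reproducible given `config$seed`; empirical category
#' shares converge to the configured prevalences as `n` grows.
#'
#' @param config a [cohort_config()].
#' @return respondent data.frame (see [code_exposures()] for the schema).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n
  sex <- ifelse(stats::runif(n) < config$sex_split, "male", "female")
  rho <- config$latent_rho
  z <- stats::rnorm(n)  # shared unhealthy-propensity latent

  out <- data.frame(id = seq_len(n), sex = sex)
  num_na <- rep(NA_real_, n)
  out$age <- num_na
  out$smoking_status <- rep(NA_character_, n)
  out$cigs_per_day <- num_na
  out$lifetime_cigs_lt_100 <- rep(NA, n)
  out$years_since_quit <- num_na
  out$drinks_last_week <- num_na
  out$max_drinks_any_day_last_week <- num_na
  out$weekly_binge <- rep(NA, n)
  out$mets_per_day <- num_na
  out$fruit_veg_freq_per_day <- num_na
  out$juice_freq_per_day <- num_na
  out$potato_freq_per_week <- num_na
  out$carrot_freq_per_week <- num_na
  out$material_quintile <- rep(NA_integer_, n)
  out$social_quintile <- rep(NA_integer_, n)
  out$education <- rep(NA_character_, n)
  out$years_since_immigration <- rep(NA_character_, n)
  out$heart_disease <- rep(NA, n)
  out$stroke <- rep(NA, n)
  out$cancer <- rep(NA, n)
  out$diabetes <- rep(NA, n)
  out$bmi_ge_35 <- rep(NA, n)
  out$weight <- num_na

  for (s in c("male", "female")) {
    i <- which(sex == s)
    if (!length(i)) next
    p <- config$prevalences[[s]]
    m <- length(i)
    zi <- z[i]

    out$age[i] <- round(20 + 79 * stats::rbeta(m, p$age_shape1, p$age_shape2))

    smk <- cut_categories(correlated_uniform(zi, rho), p$smoking)
    cur <- smk %in% c("light", "heavy")
    fmr <- smk %in% c("former_light", "former_heavy")
    out$smoking_status[i] <- ifelse(cur, "current",
                                    ifelse(fmr, "former", "never"))
    heavy_amt <- smk %in% c("heavy", "former_heavy")
    out$cigs_per_day[i] <- ifelse(
      smk == "non", NA,
      ifelse(heavy_amt, 20 + stats::rpois(m, 8),
             pmax(1, stats::rpois(m, 9))))
    out$cigs_per_day[i] <- pmin(out$cigs_per_day[i],
                                ifelse(heavy_amt, Inf, 19))
    out$lifetime_cigs_lt_100[i] <- smk == "non" & out$smoking_status[i] != "never"
    out$years_since_quit[i] <- ifelse(
      fmr, pmin(pmax(0, out$age[i] - 20),
                round(stats::rgamma(m, shape = 2, scale = 7), 1)), NA)

    alc <- cut_categories(correlated_uniform(zi, rho), p$alcohol)
    weekly_cut <- if (s == "male") 21 else 14
    mod_lo <- if (s == "male") 4 else 3
    drinks <- integer(m)
    drinks[alc == "light_non"] <- sample(0:(mod_lo - 1),
                                         sum(alc == "light_non"), TRUE)
    drinks[alc == "moderate"] <- sample(mod_lo:weekly_cut,
                                        sum(alc == "moderate"), TRUE)
    drinks[alc == "heavy"] <- weekly_cut + 1 + stats::rpois(sum(alc == "heavy"), 6)
    out$drinks_last_week[i] <- drinks
    out$max_drinks_any_day_last_week[i] <-
      ifelse(alc == "heavy", pmin(drinks, 5 + stats::rpois(m, 2)),
             pmin(drinks, 4))
    out$weekly_binge[i] <- alc == "heavy" & stats::runif(m) < 0.5

    out$mets_per_day[i] <- stats::qlnorm(1 - correlated_uniform(zi, rho),
                                         p$mets_meanlog, p$mets_sdlog)
    out$fruit_veg_freq_per_day[i] <-
      stats::qgamma(1 - correlated_uniform(zi, rho), shape = p$fv_shape,
                    scale = p$fv_scale)
    out$juice_freq_per_day[i] <- stats::rexp(m, rate = p$juice_rate)
    out$potato_freq_per_week[i] <- stats::rgamma(m, shape = p$potato_shape,
                                                 scale = p$potato_scale)
    out$carrot_freq_per_week[i] <-
      ifelse(stats::runif(m) < p$carrot_p0, 0,
             stats::rgamma(m, shape = 2, scale = 1))

    out$material_quintile[i] <-
      findInterval(correlated_uniform(zi, rho), seq(0.2, 0.8, 0.2)) + 1L
    out$social_quintile[i] <-
      findInterval(correlated_uniform(zi, rho), seq(0.2, 0.8, 0.2)) + 1L
    out$education[i] <- cut_categories(correlated_uniform(zi, rho), p$education)
    out$years_since_immigration[i] <-
      cut_categories(stats::runif(m), p$immigration)
    for (d in names(p$disease))
      out[[d]][i] <- stats::runif(m) < p$disease[[d]]
    out$bmi_ge_35[i] <- stats::runif(m) < p$bmi_ge_35

    w <- stats::rlnorm(m, meanlog = 0, sdlog = config$weight_sdlog)
    out$weight[i] <- w * config$pop_total[[s]] / sum(w)
  }
  out
}

# Gompertz cumulative hazard from age a0 to a1 for the reference pattern
gompertz_cumhaz <- function(rate20, slope, a0, a1) {
  rate20 / slope * (exp(slope * (a1 - 20)) - exp(slope * (a0 - 20)))
}

#' Ground-truth linear predictor for coded exposures
#'
#' @param coded coded exposure table ([code_exposures()]).
#' @param config a [cohort_config()] whose `true_log_hr` supplies the
#'   coefficients.
#' @return numeric vector of true log hazard ratios relative to the reference
#'   covariate pattern.
#' @export
true_linear_predictor <- function(coded, config) {
  X <- exposure_design(coded, model_spec("male"))
  beta <- config$true_log_hr[colnames(X)]
  if (anyNA(beta)) stop("true_log_hr missing terms: ",
                        paste(colnames(X)[is.na(beta)], collapse = ", "))
  drop(X %*% beta)
}

#' Simulate mortality follow-up under the ground-truth hazard
#'
#' Event ages are drawn from the sex-specific Gompertz baseline hazard on the
#' age scale multiplied by `exp(true linear predictor)`; follow-up is censored
#' administratively at `config$horizon` years.
#'
#' @param cohort respondent data.frame from [generate_cohort()].
#' @param config the generating [cohort_config()].
#' @return `cohort` with `followup_years` and `died` columns added.
#' @export
simulate_followup <- function(cohort, config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed + 1L)
  coded <- code_exposures(cohort)
  if (nrow(coded) != nrow(cohort))
    stop("cohort contains incomplete records; simulate_followup expects ",
         "generator output")
  lp <- true_linear_predictor(coded, config)
  rate20 <- config$baseline$rate20[coded$sex]
  g <- config$baseline$slope
  e <- stats::rexp(nrow(coded))
  # solve rate20/g * (exp(g(ad-20)) - exp(g(a0-20))) * exp(lp) = e for ad
  a0 <- coded$age
  ad <- 20 + log(exp(g * (a0 - 20)) + g * e * exp(-lp) / rate20) / g
  t <- ad - a0
  cohort$died <- t <= config$horizon
  cohort$followup_years <- pmin(t, config$horizon)
  cohort
}

#' Exact annual death risk implied by the generator's truth
#'
#' One-year death probability for each coded respondent, computed in closed
#' form from the Gompertz baseline and true log hazard ratios:
#' `q = 1 - exp(-(H0(age+1) - H0(age)) * exp(LP))`.
#'
#' @param coded coded exposure table.
#' @param config the generating [cohort_config()].
#' @param horizon risk horizon in years (default 1).
#' @return numeric vector of death probabilities.
#' @export
exact_risk <- function(coded, config, horizon = 1) {
  lp <- true_linear_predictor(coded, config)
  rate20 <- config$baseline$rate20[coded$sex]
  h0 <- gompertz_cumhaz(rate20, config$baseline$slope, coded$age,
                        coded$age + horizon)
  1 - exp(-h0 * exp(lp))
}

#' Observed age-sex mortality-rate table from the generator's truth
#'
#' Produces the external "observed" rate table used to exercise
#' recalibration: the survey-weighted mean of the exact annual death risks in
#' each age bin and sex, computed on a large cohort drawn from `config`,
#' optionally perturbed by a multiplicative factor.
#'
#' @param config a [cohort_config()].
#' @param age_bins data.frame of `age_lo`/`age_hi` (default the life-table
#'   5-year bins).
#' @param n cohort size used to compute the rates.
#' @param perturb multiplicative perturbation applied to all rates.
#' @return data.frame with columns `sex`, `age_lo`, `age_hi`, `rate`; bins
#'   with no respondents carry `NA` rates.
#' @export
observed_rate_table <- function(config, age_bins = age_bins_5y(),
                                n = 200000, perturb = 1) {
  big <- config
  big$n <- n
  big$seed <- (config$seed + 104729L) %% .Machine$integer.max
  coded <- code_exposures(generate_cohort(big))
  q <- exact_risk(coded, config)
  out <- expand.grid(sex = c("male", "female"),
                     age_lo = age_bins$age_lo, stringsAsFactors = FALSE)
  out <- merge(out, age_bins, by = "age_lo")
  out <- out[order(out$sex, out$age_lo), c("sex", "age_lo", "age_hi")]
  out$rate <- mapply(function(s, lo, hi) {
    i <- coded$sex == s & coded$age >= lo & coded$age <= hi
    if (!any(i)) return(NA_real_)
    weighted_mean(q[i], coded$weight[i])
  }, out$sex, out$age_lo, out$age_hi) * perturb
  rownames(out) <- NULL
  out
}

#' Exact behavioural burden implied by the generator's truth
#'
#' Computes the generator's own counterfactual: exact annual risks under the
#' configured truth for a large cohort, with and without healthy-reference
#' recoding of the requested behaviours, aggregated to attributable deaths
#' and life expectancy exactly as the estimation pipeline does. Serves as the
#' ground-truth oracle for burden recovery tests.
#'
#' @param config a [cohort_config()].
#' @param behaviours behaviours to delete (subset of smoking, alcohol,
#'   activity, diet).
#' @param n cohort size used for the truth computation.
#' @return data.frame, one row per sex, with baseline/reference deaths and
#'   life expectancy and the derived burden measures.
#' @export
true_burden <- function(config, behaviours = c("smoking", "alcohol",
                                               "activity", "diet"),
                        n = 200000) {
  big <- config
  big$n <- n
  big$seed <- (config$seed + 15485863L) %% .Machine$integer.max
  coded <- code_exposures(generate_cohort(big))
  cf <- healthy_reference(coded, behaviours)
  q0 <- exact_risk(coded, config)
  q1 <- exact_risk(cf, config)
  out <- lapply(c("male", "female"), function(s) {
    i <- coded$sex == s
    w <- coded$weight[i]
    lt0 <- build_life_table(aggregate_interval_q(q0[i], coded$age[i], w))
    lt1 <- build_life_table(aggregate_interval_q(q1[i], coded$age[i], w))
    burden_measures(sex = s,
                    baseline_deaths = sum(w * q0[i]),
                    reference_deaths = sum(w * q1[i]),
                    baseline_le = life_expectancy(lt0),
                    reference_le = life_expectancy(lt1))
  })
  do.call(rbind, out)
}
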