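#' Model specification for a sex-specific hazard model
#'
#' Describes which covariate groups enter the proportional-hazards model and
#' which behaviour groups get an age interaction. Age itself is the time scale
#' of the model (the baseline hazard carries the age effect), so it is always
#' "present" without appearing as a covariate group.
#'
#' @param sex "male" or "female".
#' @param factors covariate groups to include. Behaviour groups are
#'   `smoking` (four indicators plus continuous time since quit), `alcohol`
#'   (moderate/heavy indicators), `activity` (METs/day, continuous), `diet`
#'   (score, continuous); adjustment groups are `deprivation`, `education`,
#'   `immigration`, `disease` (four chronic-condition flags) and `bmi`.
#' @param interactions behaviour groups whose design columns are additionally
#'   multiplied by (entry age - 50) years.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(sex,
                       factors = c("smoking", "alcohol", "activity", "diet",
                                   "deprivation", "education", "immigration",
                                   "disease", "bmi"),
                       interactions = character()) {
  sex <- match.arg(sex, c("male", "female"))
  known <- names(factor_columns())
  bad <- setdiff(factors, known)
  if (length(bad)) stop("unknown factor group(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(interactions, intersect(factors, behaviour_groups()))
  if (length(bad))
    stop("interactions must name included behaviour groups: ",
         paste(bad, collapse = ", "))
  structure(list(sex = sex, factors = factors, interactions = interactions),
            class = "model_spec")
}

#' The four modelled health-behaviour groups
#'
#' @return `c("smoking", "alcohol", "activity", "diet")` — the covariate
#'   groups eligible for age interactions and counterfactual deletion.
#' @export
behaviour_groups <- function() c("smoking", "alcohol", "activity", "diet")

factor_columns <- function() {
  list(
    smoking = c("smoking_former_light", "smoking_former_heavy",
                "smoking_light", "smoking_heavy", "time_since_quit"),
    alcohol = c("alcohol_moderate", "alcohol_heavy"),
    activity = "mets_per_day",
    diet = "diet_score",
    deprivation = c("deprivation_low", "deprivation_high"),
    education = c("education_hs_grad", "education_lt_hs"),
    immigration = c("immigration_0_15", "immigration_16_30",
                    "immigration_31_45"),
    disease = c("heart_disease", "stroke", "cancer", "diabetes"),
    bmi = "bmi_ge_35"
  )
}

#' Design matrix for coded exposures under a model specification
#'
#' Expands a coded exposure table (from [code_exposures()]) into the numeric
#' covariate matrix of the proportional-hazards model: dummy indicators
#' against the reference categories (non-smoker; light/non drinker; moderate
#' deprivation; post-secondary education; long-term resident/born), continuous
#' METs/day, diet score and time since quit, and optional
#' (age - 50) x behaviour interaction columns.
#'
#' @param coded coded exposure data.frame.
#' @param spec a [model_spec()].
#' @return numeric matrix, one row per respondent.
#' @export
exposure_design <- function(coded, spec) {
  stopifnot(inherits(spec, "model_spec"))
  base <- list(
    smoking_former_light = coded$smoking_class == "former_light",
    smoking_former_heavy = coded$smoking_class == "former_heavy",
    smoking_light = coded$smoking_class == "light",
    smoking_heavy = coded$smoking_class == "heavy",
    time_since_quit = coded$time_since_quit,
    alcohol_moderate = coded$alcohol_class == "moderate",
    alcohol_heavy = coded$alcohol_class == "heavy",
    mets_per_day = coded$mets_per_day,
    diet_score = coded$diet_score,
    deprivation_low = coded$deprivation == "low",
    deprivation_high = coded$deprivation == "high",
    education_hs_grad = coded$education == "hs_grad",
    education_lt_hs = coded$education == "lt_hs",
    immigration_0_15 = coded$years_since_immigration == "0_15",
    immigration_16_30 = coded$years_since_immigration == "16_30",
    immigration_31_45 = coded$years_since_immigration == "31_45",
    heart_disease = coded$heart_disease,
    stroke = coded$stroke,
    cancer = coded$cancer,
    diabetes = coded$diabetes,
    bmi_ge_35 = coded$bmi_ge_35
  )
  cols <- factor_columns()
  keep <- unlist(cols[spec$factors], use.names = FALSE)
  X <- vapply(base[keep], as.numeric, numeric(nrow(coded)))
  if (nrow(coded) == 1L) X <- matrix(X, nrow = 1, dimnames = list(NULL, keep))
  for (g in spec$interactions) {
    gi <- X[, cols[[g]], drop = FALSE] * (coded$age - 50)
    colnames(gi) <- paste0("agex_", cols[[g]])
    X <- cbind(X, gi)
  }
  X
}

#' Five-year age intervals of the abridged life table
#'
#' @return data.frame with `age_lo` (20, 25, ..., 95) and `age_hi`
#'   (24, ..., 99); intervals are [age_lo, age_lo + 5).
#' @export
age_bins_5y <- function() {
  lo <- seq(20, 95, by = 5)
  data.frame(age_lo = lo, age_hi = lo + 4)
}

# interval index (1..16) for an age, NA outside 20-99
age_bin_index <- function(age) {
  i <- findInterval(age, seq(20, 100, by = 5))
  i[age < 20 | age >= 100] <- NA_integer_
  i
}

weighted_mean <- function(x, w) sum(w * x) / sum(w)
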