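#' Healthy-reference counterfactual recoding
#'
#' Recodes the listed behaviours of a coded exposure table to their healthy
#' reference levels, leaving everything else (age, sociodemographics,
#' diseases, BMI) unchanged: smoking — everyone becomes a non-smoker with
#' time since quit zeroed; activity — METs/day raised to 3 where below;
#' diet — score raised to 8 where below; alcohol — heavy drinkers become
#' light/non-drinkers. Respondents already at the reference are untouched.
#'
#' @param coded coded exposure table.
#' @param behaviours non-empty subset of `c("smoking", "alcohol",
#'   "activity", "diet")`.
#' @return the counterfactual coded table.
#' @export
healthy_reference <- function(coded, behaviours) {
  if (!length(behaviours)) stop("behaviours must be non-empty")
  behaviours <- match.arg(behaviours, behaviour_groups(), several.ok = TRUE)
  if ("smoking" %in% behaviours) {
    coded$smoking_class[] <- "non"
    coded$time_since_quit <- 0
  }
  if ("alcohol" %in% behaviours)
    coded$alcohol_class[coded$alcohol_class == "heavy"] <- "light_non"
  if ("activity" %in% behaviours)
    coded$mets_per_day <- pmax(coded$mets_per_day, 3)
  if ("diet" %in% behaviours)
    coded$diet_score <- pmax(coded$diet_score, 8)
  coded
}

#' Burden measures from baseline and counterfactual components
#'
#' The reporting identities tying a burden estimate together: attributable
#' deaths are baseline minus reference deaths, the attributable fraction is
#' attributable over baseline deaths, and life expectancy lost is reference
#' minus baseline life expectancy.
#'
#' @param sex label carried into the output.
#' @param baseline_deaths,reference_deaths weighted annual deaths under
#'   actual and healthy-reference exposures.
#' @param baseline_le,reference_le life expectancy (full lifespan scale)
#'   under actual and healthy-reference exposures.
#' @return one-row data.frame with the inputs plus `attributable_deaths`,
#'   `attributable_fraction`, and `le_lost`.
#' @export
burden_measures <- function(sex, baseline_deaths, reference_deaths,
                            baseline_le, reference_le) {
  ad <- baseline_deaths - reference_deaths
  data.frame(sex = sex,
             baseline_deaths = baseline_deaths,
             reference_deaths = reference_deaths,
             attributable_deaths = ad,
             attributable_fraction = if (baseline_deaths > 0)
               ad / baseline_deaths else 0,
             baseline_le = baseline_le,
             reference_le = reference_le,
             le_lost = reference_le - baseline_le)
}

# per-sex burden computation on coded rows of one sex
burden_one_sex <- function(alg, coded, behaviours) {
  q0 <- predict_risk(alg, coded, 1)
  cf <- healthy_reference(coded, behaviours)
  q1 <- predict_risk(alg, cf, 1)
  w <- coded$weight
  lt0 <- build_life_table(aggregate_interval_q(q0, coded$age, w))
  lt1 <- build_life_table(aggregate_interval_q(q1, coded$age, w))
  out <- burden_measures(as.character(coded$sex[1]),
                         baseline_deaths = sum(w * q0),
                         reference_deaths = sum(w * q1),
                         baseline_le = life_expectancy(lt0),
                         reference_le = life_expectancy(lt1))
  attr(out, "life_tables") <- list(baseline = lt0, reference = lt1)
  out
}

#' Estimate the mortality burden of unhealthy behaviours
#'
#' For each sex: annual (1-year) calibrated risks are predicted for the
#' survey as reported (baseline) and after healthy-reference recoding of the
#' requested behaviours (counterfactual); weighted sums give baseline,
#' reference, and attributable deaths; survey-weighted abridged life tables
#' on each risk set give baseline and reference life expectancy and the life
#' expectancy lost.
#'
#' @param algorithms per-sex `risk_algorithm` list (see [apply_to_survey()]).
#' @param survey respondent table or coded exposure table.
#' @param behaviours behaviours to delete (default all four).
#' @return data.frame of class `burden_estimate`, one row per sex present;
#'   attribute `"life_tables"` holds the per-sex baseline/reference tables,
#'   attribute `"calibrated"` records whether any algorithm carried
#'   non-unit calibration factors.
#' @export
burden_estimate <- function(algorithms, survey,
                            behaviours = behaviour_groups()) {
  coded <- if (!is.null(survey$smoking_class)) survey
           else code_exposures(survey)
  sexes <- intersect(c("male", "female"), unique(as.character(coded$sex)))
  lts <- list()
  rows <- lapply(sexes, function(s) {
    alg <- get_algorithm(algorithms, s)
    r <- burden_one_sex(alg, coded[coded$sex == s, , drop = FALSE], behaviours)
    lts[[s]] <<- attr(r, "life_tables")
    r
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  calibrated <- any(vapply(sexes, function(s)
    any(get_algorithm(algorithms, s)$calibration$factor != 1), logical(1)))
  structure(out, life_tables = lts, behaviours = behaviours,
            calibrated = calibrated,
            class = c("burden_estimate", "data.frame"))
}

#' Life expectancy for a health-behaviour profile
#'
#' Either subsets the survey to respondents matching a profile and builds
#' their life table, or (fixed-vector mode) builds a life table directly from
#' a single coded covariate row evaluated at every interval midpoint age.
#' The packaged profiles follow published recommendation levels: `"healthy"`
#' is non-smoking, not heavy-drinking, at least 3 METs/day, diet score at
#' least 8; `"unhealthy"` is heavy smoking, heavy drinking, under 1.5
#' METs/day, diet score under 2.
#'
#' @param algorithms per-sex `risk_algorithm` list.
#' @param survey respondent or coded table (ignored in fixed-vector mode).
#' @param profile `"healthy"`, `"unhealthy"`, a function
#'   `f(coded) -> logical`, or a one-row coded data.frame (fixed-vector
#'   mode; its `sex` selects the algorithm).
#' @return data.frame with `sex`, `n`, and `le`.
#' @export
profile_life_expectancy <- function(algorithms, survey, profile = "healthy") {
  if (is.data.frame(profile)) {
    stopifnot(nrow(profile) == 1)
    s <- as.character(profile$sex[1])
    alg <- get_algorithm(algorithms, s)
    mids <- age_bins_5y()$age_lo + 2.5
    rows <- profile[rep(1, length(mids)), , drop = FALSE]
    rows$age <- mids
    q1 <- predict_risk(alg, rows, 1)
    lt <- build_life_table(1 - (1 - q1)^5)
    return(data.frame(sex = s, n = 1, le = life_expectancy(lt)))
  }
  sel_fun <- if (is.function(profile)) profile
  else switch(match.arg(profile, c("healthy", "unhealthy")),
    healthy = function(d) d$smoking_class == "non" &
      d$alcohol_class != "heavy" & d$mets_per_day >= 3 & d$diet_score >= 8,
    unhealthy = function(d) d$smoking_class == "heavy" &
      d$alcohol_class == "heavy" & d$mets_per_day < 1.5 & d$diet_score < 2)
  coded <- if (!is.null(survey$smoking_class)) survey
           else code_exposures(survey)
  sexes <- intersect(c("male", "female"), unique(as.character(coded$sex)))
  rows <- lapply(sexes, function(s) {
    d <- coded[coded$sex == s & sel_fun(coded), , drop = FALSE]
    if (!nrow(d)) stop("no ", s, " respondents match the profile")
    alg <- get_algorithm(algorithms, s)
    q1 <- predict_risk(alg, d, 1)
    lt <- build_life_table(aggregate_interval_q(q1, d$age, d$weight))
    data.frame(sex = s, n = nrow(d), le = life_expectancy(lt))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Behavioural burden by sociodemographic or behavioural group (equity table)
#'
#' Computes one burden estimate per level of a grouping variable within each
#' sex: attributable fraction of annual deaths, baseline and
#' behaviour-deleted life expectancy, and life expectancy lost — the shape
#' used to examine burden from an equity perspective.
#'
#' @param algorithms per-sex `risk_algorithm` list.
#' @param survey respondent or coded table.
#' @param group name of a coded grouping column (`"education"`,
#'   `"deprivation"`, `"smoking_class"`, `"alcohol_class"`,
#'   `"years_since_immigration"`).
#' @param behaviours behaviours to delete.
#' @param min_group groups smaller than this are flagged.
#' @return data.frame: `sex`, `group`, `n`, `attributable_fraction`,
#'   `baseline_le`, `reference_le`, `le_lost`, `flag_small`.
#' @export
equity_table <- function(algorithms, survey, group,
                         behaviours = behaviour_groups(), min_group = 50) {
  coded <- if (!is.null(survey$smoking_class)) survey
           else code_exposures(survey)
  if (!group %in% names(coded)) stop("no grouping column ", group)
  g <- coded[[group]]
  sexes <- intersect(c("male", "female"), unique(as.character(coded$sex)))
  rows <- list()
  for (s in sexes) {
    alg <- get_algorithm(algorithms, s)
    for (lev in levels(factor(g))) {
      d <- coded[coded$sex == s & !is.na(g) & g == lev, , drop = FALSE]
      if (!nrow(d)) next
      b <- burden_one_sex(alg, d, behaviours)
      rows[[paste(s, lev)]] <- data.frame(
        sex = s, group = lev, n = nrow(d),
        attributable_fraction = b$attributable_fraction,
        baseline_le = b$baseline_le, reference_le = b$reference_le,
        le_lost = b$le_lost, flag_small = nrow(d) < min_group)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
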