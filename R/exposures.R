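#' Code smoking behaviour into model categories
#'
#' Combines smoking status, daily cigarette consumption, lifetime consumption,
#' and time since quitting into the five-level smoking classification used by
#' the risk algorithm: heavy (current, at least one pack of 20 per day), light
#' (current, under a pack), former heavy / former light (with a continuous
#' time-since-quit measure), and non-smoker (never-smoker or former occasional
#' smoker with fewer than 100 lifetime cigarettes).
#'
#' Current smokers with no reported daily amount (occasional smokers) are coded
#' light. Former smokers with fewer than 100 lifetime cigarettes are coded
#' non-smokers with time since quit set to zero.
#'
#' @param status character vector: "current", "former" or "never".
#' @param cigs_per_day cigarettes per day (current: current amount; former:
#'   amount when smoking). May be `NA` for occasional/never smokers.
#' @param lifetime_cigs_lt_100 logical; fewer than 100 cigarettes ever smoked.
#' @param years_since_quit years since quitting (former smokers only).
#' @return data.frame with columns `smoking_class` (factor: heavy, light,
#'   former_heavy, former_light, non) and `time_since_quit` (years; 0 except
#'   for former classes). Rows that cannot be classified (missing required
#'   fields) get `NA` in both columns.
#' @export
code_smoking <- function(status, cigs_per_day, lifetime_cigs_lt_100,
                         years_since_quit) {
  n <- max(length(status), length(cigs_per_day),
           length(lifetime_cigs_lt_100), length(years_since_quit))
  status <- rep_len(status, n)
  cigs_per_day <- rep_len(as.numeric(cigs_per_day), n)
  lifetime_cigs_lt_100 <- rep_len(as.logical(lifetime_cigs_lt_100), n)
  years_since_quit <- rep_len(as.numeric(years_since_quit), n)
  if (any(cigs_per_day < 0, na.rm = TRUE))
    stop("cigs_per_day must be non-negative")

  cls <- rep(NA_character_, n)
  tsq <- rep(NA_real_, n)

  never <- !is.na(status) & status == "never"
  cls[never] <- "non"
  tsq[never] <- 0

  cur <- !is.na(status) & status == "current"
  # occasional current smokers (no daily amount) are light by convention
  cls[cur] <- ifelse(!is.na(cigs_per_day[cur]) & cigs_per_day[cur] >= 20,
                     "heavy", "light")
  tsq[cur] <- 0

  fmr <- !is.na(status) & status == "former"
  occ <- fmr & !is.na(lifetime_cigs_lt_100) & lifetime_cigs_lt_100
  cls[occ] <- "non"
  tsq[occ] <- 0
  fdaily <- fmr & !occ
  ok <- fdaily & !is.na(cigs_per_day) & !is.na(years_since_quit) &
    years_since_quit >= 0
  cls[ok] <- ifelse(cigs_per_day[ok] >= 20, "former_heavy", "former_light")
  tsq[ok] <- years_since_quit[ok]

  data.frame(
    smoking_class = factor(cls, levels = smoking_levels()),
    time_since_quit = tsq
  )
}

smoking_levels <- function() {
  c("non", "former_light", "former_heavy", "light", "heavy")
}

#' Code weekly alcohol consumption into drinking categories
#'
#' Heavy drinking is triggered by any of: more than 21 (men) or 14 (women)
#' drinks in the previous week; 5 or more drinks on any single day in the
#' previous week; or bingeing (5+ drinks on one occasion) on a weekly basis.
#' Moderate is 4 to 21 (men) or 3 to 14 (women) drinks per week; light/non is
#' 0 to 3 (men) or 0 to 2 (women).
#'
#' @param sex "male" or "female".
#' @param drinks_last_week total drinks in the previous week.
#' @param max_drinks_any_day most drinks on any single day in the previous week.
#' @param weekly_binge logical; binge drinking on a weekly basis.
#' @return factor with levels light_non, moderate, heavy.
#' @export
code_alcohol <- function(sex, drinks_last_week, max_drinks_any_day,
                         weekly_binge) {
  n <- max(length(sex), length(drinks_last_week),
           length(max_drinks_any_day), length(weekly_binge))
  sex <- rep_len(sex, n)
  drinks <- rep_len(as.numeric(drinks_last_week), n)
  mx <- rep_len(as.numeric(max_drinks_any_day), n)
  binge <- rep_len(as.logical(weekly_binge), n)
  if (any(drinks < 0 | mx < 0, na.rm = TRUE))
    stop("drink counts must be non-negative")

  weekly_cut <- ifelse(sex == "male", 21, 14)  # heavy: strictly greater
  mod_lo <- ifelse(sex == "male", 4, 3)

  heavy <- drinks > weekly_cut | mx >= 5 | binge
  moderate <- !heavy & drinks >= mod_lo
  cls <- ifelse(is.na(heavy) | is.na(drinks), NA_character_,
                ifelse(heavy, "heavy",
                       ifelse(moderate, "moderate", "light_non")))
  factor(cls, levels = c("light_non", "moderate", "heavy"))
}

#' Average daily leisure-time energy expenditure (METs/day)
#'
#' Daily averaged metabolic-equivalent value over the previous month's
#' self-reported leisure-time physical activities. Each activity contributes
#' `met_value * times_per_month * minutes_per_session / 60 / 30`
#' (MET-hours converted to a per-day average over a 30-day month).
#'
#' @param activity_records data.frame with columns `met_value`
#'   (kcal/kg/h), `times_per_month`, and `minutes_per_session`; an empty or
#'   `NULL` record set yields 0.
#' @return non-negative scalar, METs/day.
#' @export
mets_per_day <- function(activity_records) {
  if (is.null(activity_records) || nrow(activity_records) == 0) return(0)
  with(activity_records, {
    if (any(times_per_month < 0 | minutes_per_session < 0 | met_value < 0))
      stop("activity records must be non-negative")
    sum(met_value * times_per_month * minutes_per_session / 60) / 30
  })
}

#' Diet quality score (0 to 10)
#'
#' Score = 2 baseline points, plus 1 point per daily frequency of fruit and
#' vegetable consumption excluding juice (capped at 8 points), minus 2 points
#' for high potato intake (7+/week for men, 5+/week for women), minus 2 points
#' for no carrot intake, minus 2 points per daily juice frequency above
#' once/day (capped at -10). Negative totals are recoded to 0 and the score is
#' capped at 10.
#'
#' @param sex "male" or "female".
#' @param fruit_veg_freq_per_day daily frequency of fruit/vegetable intake
#'   (juice excluded).
#' @param juice_freq_per_day daily frequency of fruit juice intake.
#' @param potato_freq_per_week weekly frequency of potato intake.
#' @param carrot_freq_per_week weekly frequency of carrot intake.
#' @return numeric score in [0, 10].
#' @export
diet_score <- function(sex, fruit_veg_freq_per_day, juice_freq_per_day,
                       potato_freq_per_week, carrot_freq_per_week) {
  n <- max(length(sex), length(fruit_veg_freq_per_day),
           length(juice_freq_per_day), length(potato_freq_per_week),
           length(carrot_freq_per_week))
  sex <- rep_len(sex, n)
  fv <- rep_len(as.numeric(fruit_veg_freq_per_day), n)
  juice <- rep_len(as.numeric(juice_freq_per_day), n)
  potato <- rep_len(as.numeric(potato_freq_per_week), n)
  carrot <- rep_len(as.numeric(carrot_freq_per_week), n)
  if (any(c(fv, juice, potato, carrot) < 0, na.rm = TRUE))
    stop("diet frequencies must be non-negative")

  potato_cut <- ifelse(sex == "male", 7, 5)
  raw <- 2 +
    pmin(fv, 8) -
    2 * (potato >= potato_cut) -
    2 * (carrot == 0) +
    pmax(-10, -2 * pmax(0, juice - 1))
  pmin(10, pmax(0, raw))
}

#' Neighbourhood deprivation category from deprivation-index quintiles
#'
#' Cross-tabulates material and social deprivation quintiles (1 = least
#' deprived, 5 = most deprived). Both quintiles in the first or second
#' quintile (4 cells) is low deprivation; both in the fourth or fifth (4
#' cells) is high; the remaining 17 cells are moderate.
#'
#' @param material_quintile,social_quintile integers 1 to 5.
#' @return factor with levels low, moderate, high.
#' @export
deprivation_category <- function(material_quintile, social_quintile) {
  m <- as.integer(material_quintile)
  s <- as.integer(social_quintile)
  bad <- (!is.na(m) & (m < 1 | m > 5)) | (!is.na(s) & (s < 1 | s > 5))
  if (any(bad)) stop("deprivation quintiles must be in 1..5")
  cls <- ifelse(is.na(m) | is.na(s), NA_character_,
                ifelse(m <= 2 & s <= 2, "low",
                       ifelse(m >= 4 & s >= 4, "high", "moderate")))
  factor(cls, levels = c("low", "moderate", "high"))
}

respondent_required_fields <- function() {
  list(
    demographics = c("sex", "age", "weight"),
    smoking = c("smoking_status"),
    alcohol = c("drinks_last_week", "max_drinks_any_day_last_week",
                "weekly_binge"),
    activity = c("mets_per_day"),
    diet = c("fruit_veg_freq_per_day", "juice_freq_per_day",
             "potato_freq_per_week", "carrot_freq_per_week"),
    deprivation = c("material_quintile", "social_quintile"),
    sociodemographic = c("education", "years_since_immigration"),
    disease = c("heart_disease", "stroke", "cancer", "diabetes", "bmi_ge_35")
  )
}

#' Build coded exposure vectors for a respondent table
#'
#' Applies all exposure-coding rules ([code_smoking()], [code_alcohol()],
#' [diet_score()], [deprivation_category()]) to a respondent table and returns
#' one coded row per complete record. Records missing any model field are
#' excluded (complete-case rule) and logged with the reason in the
#' `"exclusions"` attribute.
#'
#' @param respondents data.frame in the survey schema (see [read_survey()] and
#'   the packaged data dictionary). An `activity_records` list-column, if
#'   present and `mets_per_day` is missing, is reduced with [mets_per_day()].
#' @return data.frame of coded exposures (one row per included respondent):
#'   `id`, `sex`, `age`, `weight`, `smoking_class`, `time_since_quit`,
#'   `alcohol_class`, `mets_per_day`, `diet_score`, `deprivation`,
#'   `education`, `years_since_immigration`, disease flags, `bmi_ge_35`, and
#'   `followup_years`/`died` when present. Attribute `"exclusions"` is a
#'   data.frame of (id, reason).
#' @export
code_exposures <- function(respondents) {
  r <- as.data.frame(respondents)
  n <- nrow(r)
  if (is.null(r$id)) r$id <- seq_len(n)
  if (!is.null(r$activity_records) && is.null(r$mets_per_day))
    r$mets_per_day <- vapply(r$activity_records, mets_per_day, numeric(1))

  req <- respondent_required_fields()
  missing_cols <- setdiff(unlist(req), names(r))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))

  # validation-level failures
  reason <- rep(NA_character_, n)
  flag <- function(bad, why) {
    bad <- !is.na(bad) & bad
    reason[is.na(reason) & bad] <<- why
  }
  flag(is.na(r$sex) | !(r$sex %in% c("male", "female")), "invalid:sex")
  flag(is.na(r$age) | r$age < 20 | r$age > 99, "invalid:age")
  flag(is.na(r$weight) | r$weight <= 0, "invalid:weight")

  smoking <- code_smoking(r$smoking_status, r$cigs_per_day,
                          r$lifetime_cigs_lt_100, r$years_since_quit)
  flag(is.na(smoking$smoking_class), "missing:smoking")
  alcohol <- code_alcohol(r$sex, r$drinks_last_week,
                          r$max_drinks_any_day_last_week, r$weekly_binge)
  flag(is.na(alcohol), "missing:alcohol")
  flag(is.na(r$mets_per_day), "missing:activity")
  diet <- diet_score(r$sex, r$fruit_veg_freq_per_day, r$juice_freq_per_day,
                     r$potato_freq_per_week, r$carrot_freq_per_week)
  flag(is.na(diet), "missing:diet")
  depr <- deprivation_category(r$material_quintile, r$social_quintile)
  flag(is.na(depr), "missing:deprivation")
  flag(is.na(r$education) |
         !(r$education %in% c("lt_hs", "hs_grad", "post_sec")),
       "missing:education")
  flag(is.na(r$years_since_immigration) |
         !(r$years_since_immigration %in% immigration_levels()),
       "missing:immigration")
  for (d in req$disease) flag(is.na(r[[d]]), paste0("missing:", d))
  if (!is.null(r$followup_years))
    flag(!is.na(r$followup_years) & r$followup_years < 0, "invalid:followup")

  keep <- is.na(reason)
  out <- data.frame(
    id = r$id[keep],
    sex = factor(r$sex[keep], levels = c("male", "female")),
    age = as.numeric(r$age[keep]),
    weight = as.numeric(r$weight[keep]),
    smoking_class = smoking$smoking_class[keep],
    time_since_quit = smoking$time_since_quit[keep],
    alcohol_class = alcohol[keep],
    mets_per_day = as.numeric(r$mets_per_day[keep]),
    diet_score = diet[keep],
    deprivation = depr[keep],
    education = factor(r$education[keep],
                       levels = c("post_sec", "hs_grad", "lt_hs")),
    years_since_immigration = factor(r$years_since_immigration[keep],
                                     levels = immigration_levels()),
    heart_disease = as.logical(r$heart_disease[keep]),
    stroke = as.logical(r$stroke[keep]),
    cancer = as.logical(r$cancer[keep]),
    diabetes = as.logical(r$diabetes[keep]),
    bmi_ge_35 = as.logical(r$bmi_ge_35[keep])
  )
  if (!is.null(r$followup_years)) out$followup_years <- r$followup_years[keep]
  if (!is.null(r$died)) out$died <- as.logical(r$died[keep])
  attr(out, "exclusions") <-
    data.frame(id = r$id[!keep], reason = reason[!keep])
  out
}

immigration_levels <- function() {
  c("gt45_or_born", "0_15", "16_30", "31_45")
}
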