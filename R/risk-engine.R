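# calibration factor for entry ages, from the algorithm's calibration table;
# ages outside the table default to 1
calibration_factor <- function(algorithm, age) {
  cal <- algorithm$calibration
  f <- rep(1, length(age))
  for (j in seq_len(nrow(cal))) {
    i <- age >= cal$age_lo[j] & age <= cal$age_hi[j]
    f[i] <- cal$factor[j]
  }
  f
}

# log baseline survival (-H0, which stays finite where exp(-H0) would
# underflow), linearly interpolated between integer grid ages
log_s0_at <- function(algorithm, age) {
  h <- algorithm$baseline_cumhaz
  if (is.null(h)) h <- -log(algorithm$baseline_s0)
  stats::approx(algorithm$baseline_age, -h, xout = age, rule = 1)$y
}

#' Predict death risk from a risk algorithm
#'
#' Risk over `horizon` years from entry age `a` is
#' `1 - (S0(a + h) / S0(a))^exp(LP)`, where `S0` is the baseline survival of
#' the algorithm (log-linearly interpolated between integer ages) and `LP`
#' the linear predictor of the coded exposures. The result is multiplied by
#' the calibration factor of the respondent's (age bin, sex) cell and clamped
#' to [0, 1].
#'
#' @param algorithm a `risk_algorithm`.
#' @param coded coded exposure rows (all of the algorithm's sex).
#' @param horizon risk horizon in years (1 for life tables and attributable
#'   deaths, 5 for the headline risk).
#' @return vector of death probabilities.
#' @export
predict_risk <- function(algorithm, coded, horizon = 5) {
  stopifnot(inherits(algorithm, "risk_algorithm"))
  if (!is.null(coded$sex) && any(coded$sex != algorithm$sex))
    stop("coded rows must all be of the algorithm's sex (", algorithm$sex, ")")
  age <- coded$age
  gmin <- min(algorithm$baseline_age)
  gmax <- max(algorithm$baseline_age)
  if (any(age < gmin) || any(age + horizon > gmax))
    stop("ages must satisfy ", gmin, " <= age and age + ", horizon,
         " <= ", gmax)
  lp <- drop(exposure_design(coded, algorithm$spec) %*% algorithm$coef)
  cumh <- log_s0_at(algorithm, age) - log_s0_at(algorithm, age + horizon)
  h <- exp(lp) * cumh
  h[cumh == 0] <- 0  # zero baseline hazard over the interval: risk is 0
  raw <- 1 - exp(-h)
  pmin(1, pmax(0, calibration_factor(algorithm, age) * raw))
}

get_algorithm <- function(algorithms, sex) {
  if (inherits(algorithms, "risk_algorithm")) {
    if (algorithms$sex != sex) stop("no algorithm for sex ", sex)
    return(algorithms)
  }
  a <- algorithms[[sex]]
  if (is.null(a)) stop("no algorithm for sex ", sex)
  stopifnot(inherits(a, "risk_algorithm"))
  a
}

#' Apply risk algorithms to an unlinked survey
#'
#' Codes a respondent table, then predicts annual and 5-year death risk for
#' every included respondent using the sex-matched algorithm. Exclusions from
#' the complete-case coding are carried through in the `"exclusions"`
#' attribute.
#'
#' @param algorithms a named list `list(male = , female = )` of
#'   `risk_algorithm` objects (either may be omitted for single-sex surveys),
#'   or a single algorithm.
#' @param respondents respondent data.frame, or an already-coded exposure
#'   table (detected by the presence of `smoking_class`).
#' @return the coded table with `risk1` and `risk5` columns appended.
#' @export
apply_to_survey <- function(algorithms, respondents) {
  coded <- if (!is.null(respondents$smoking_class)) respondents
           else code_exposures(respondents)
  coded$risk1 <- rep(NA_real_, nrow(coded))
  coded$risk5 <- rep(NA_real_, nrow(coded))
  for (s in intersect(c("male", "female"), unique(as.character(coded$sex)))) {
    alg <- get_algorithm(algorithms, s)
    i <- coded$sex == s
    coded$risk1[i] <- predict_risk(alg, coded[i, , drop = FALSE], 1)
    coded$risk5[i] <- predict_risk(alg, coded[i, , drop = FALSE], 5)
  }
  coded
}

#' Recalibrate a risk algorithm to an observed age-sex rate table
#'
#' External unlinked calibration: for each age bin of the observed table, the
#' calibration factor becomes `O / P`, where `O` is the observed annual
#' mortality rate and `P` the survey-weighted mean uncalibrated predicted
#' annual risk in the bin. After recalibration, the survey-weighted predicted
#' bin rates equal the observed rates to machine precision (as long as no
#' individual calibrated risk hits the [0, 1] clamp), and a second
#' recalibration against the same table changes nothing.
#'
#' @param algorithm a `risk_algorithm`.
#' @param coded coded survey rows of the algorithm's sex.
#' @param observed data.frame with columns `sex`, `age_lo`, `age_hi`, `rate`
#'   (annual deaths per person-year); must cover every survey age.
#' @return the recalibrated `risk_algorithm` (calibration table on the
#'   observed bins).
#' @export
recalibrate <- function(algorithm, coded, observed) {
  stopifnot(inherits(algorithm, "risk_algorithm"))
  obs <- observed[observed$sex == algorithm$sex, , drop = FALSE]
  if (!nrow(obs)) stop("observed table has no rows for sex ", algorithm$sex)
  coded <- coded[coded$sex == algorithm$sex, , drop = FALSE]

  bin_of <- rep(NA_integer_, nrow(coded))
  for (j in seq_len(nrow(obs))) {
    i <- coded$age >= obs$age_lo[j] & coded$age <= obs$age_hi[j]
    bin_of[i] <- j
  }
  if (anyNA(bin_of)) {
    miss <- sort(unique(5 * floor(coded$age[is.na(bin_of)] / 5)))
    stop("observed table missing bin(s) covering age(s): ",
         paste(miss, collapse = ", "))
  }

  uncal <- algorithm
  uncal$calibration$factor <- 1
  raw <- predict_risk(uncal, coded, 1)

  new_cal <- obs[, c("age_lo", "age_hi")]
  new_cal$factor <- NA_real_
  old_factor_mid <- calibration_factor(algorithm, (obs$age_lo + obs$age_hi) / 2)
  for (j in seq_len(nrow(obs))) {
    i <- which(bin_of == j)
    P <- if (length(i)) weighted_mean(raw[i], coded$weight[i]) else 0
    if (is.na(obs$rate[j]) || !length(i) || is.na(P) || P <= 0) {
      warning("bin ", obs$age_lo[j], "-", obs$age_hi[j],
              ": no respondents or zero predicted risk; factor unchanged")
      new_cal$factor[j] <- old_factor_mid[j]
    } else {
      new_cal$factor[j] <- obs$rate[j] / P
    }
  }
  algorithm$calibration <- new_cal
  algorithm
}
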