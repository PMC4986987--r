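#' Fit a sex-specific proportional-hazards model on the age time scale
#'
#' Fits a Cox model for all-cause death with age as the time scale: each
#' respondent enters the risk set at survey age (left truncation) and exits
#' at survey age plus follow-up. The age effect, including its non-linearity,
#' is therefore absorbed nonparametrically by the baseline hazard, and the
#' covariates are the coded behavioural and sociodemographic exposures of the
#' model specification. Ties are handled with the Efron approximation.
#'
#' @param coded coded exposure table ([code_exposures()]) including
#'   `followup_years` and `died`; only rows of `spec$sex` are used.
#' @param spec a [model_spec()].
#' @param min_deaths minimum number of deaths required to fit (default 50).
#' @param entry_offset years added to the entry age (used by the
#'   early-follow-up sensitivity refit); exit ages are unchanged.
#' @return object of class `hazard_fit`: the `survival::coxph` fit plus the
#'   spec, coefficient vector and covariance, and cohort summaries (`n`,
#'   `deaths`, `person_years`).
#' @export
fit_hazard_model <- function(coded, spec, min_deaths = 50, entry_offset = 0) {
  stopifnot(inherits(spec, "model_spec"))
  if (is.null(coded$followup_years) || is.null(coded$died))
    stop("coded cohort must carry followup_years and died")
  d <- coded[coded$sex == spec$sex, , drop = FALSE]
  if (!nrow(d)) stop("no respondents of sex ", spec$sex)
  deaths <- sum(d$died)
  if (deaths == 0) stop("cohort has no deaths")
  if (deaths < min_deaths)
    stop("only ", deaths, " deaths; minimum is ", min_deaths)

  X <- exposure_design(d, spec)
  entry <- d$age + entry_offset
  exit <- d$age + pmax(d$followup_years, entry_offset + 1 / 365.25)
  df <- data.frame(X, check.names = FALSE)
  df$.entry <- entry
  df$.exit <- exit
  df$.died <- as.integer(d$died)
  form <- stats::reformulate(sprintf("`%s`", colnames(X)),
                             response = quote(survival::Surv(.entry, .exit, .died)))
  fit <- survival::coxph(form, data = df, ties = "efron")
  if (!is.null(fit$info) && any(is.na(stats::coef(fit))))
    stop("model did not converge; iterations: ", fit$iter)
  if (any(is.na(stats::coef(fit))))
    stop("singular design: ", paste(names(stats::coef(fit))[
      is.na(stats::coef(fit))], collapse = ", "))
  beta <- stats::coef(fit)
  names(beta) <- colnames(X)
  vc <- stats::vcov(fit)
  dimnames(vc) <- list(colnames(X), colnames(X))
  structure(list(fit = fit, spec = spec, coef = beta, vcov = vc,
                 n = nrow(d), deaths = deaths,
                 person_years = sum(d$followup_years)),
            class = "hazard_fit")
}

#' @export
print.hazard_fit <- function(x, ...) {
  cat("Proportional-hazards fit (", x$spec$sex, "), age time scale\n",
      "n = ", x$n, ", deaths = ", x$deaths,
      ", person-years = ", round(x$person_years), "\n", sep = "")
  print(data.frame(log_hr = round(x$coef, 4),
                   hr = round(exp(x$coef), 3),
                   se = round(sqrt(diag(x$vcov)), 4)))
  invisible(x)
}

#' Sensitivity refit excluding early follow-up
#'
#' Refits the model excluding the first `years` of observation, to allow for
#' a healthy-respondent effect: respondents who died or were censored within
#' the window are dropped, and the remaining respondents enter the risk set
#' `years` later. `years = 0` reproduces [fit_hazard_model()].
#'
#' @inheritParams fit_hazard_model
#' @param years length of the excluded early-follow-up window.
#' @return a `hazard_fit`.
#' @export
sensitivity_refit_excluding_early_followup <- function(coded, spec, years = 2,
                                                       min_deaths = 50) {
  stopifnot(years >= 0)
  if (years == 0) return(fit_hazard_model(coded, spec, min_deaths))
  keep <- coded$followup_years > years
  if (!any(keep)) stop("window of ", years,
                       " years excludes every record")
  fit_hazard_model(coded[keep, , drop = FALSE], spec, min_deaths,
                   entry_offset = years)
}

#' Criterion-driven covariate inclusion
#'
#' Implements the prespecified model-building rule: starting from the base
#' specification, a candidate covariate group is added if, in its absence,
#' predicted and observed deaths differ by more than `threshold` (relative)
#' in at least one subgroup holding more than `min_death_share` of total
#' deaths. Each candidate is assessed by refitting the model with all other
#' candidates retained and the candidate omitted.
#'
#' @param coded coded exposure table with follow-up, one sex's rows used per
#'   `base_spec$sex`.
#' @param base_spec the base [model_spec()] (age plus health behaviours in
#'   the published procedure).
#' @param candidates character vector of candidate factor groups.
#' @param subgroups named list of functions `f(coded) -> logical` defining
#'   the policy subgroups to calibrate against.
#' @param threshold relative predicted-observed difference considered
#'   important (default 0.20).
#' @param min_death_share minimum share of total deaths for a subgroup to be
#'   assessed (default 0.05).
#' @param horizon risk horizon in years for the calibration check.
#' @param min_deaths passed to [fit_hazard_model()].
#' @return a [model_spec()] with the base factors plus every admitted
#'   candidate; attribute `"assessment"` records the per-candidate decision.
#' @export
criterion_driven_inclusion <- function(coded, base_spec, candidates,
                                       subgroups, threshold = 0.20,
                                       min_death_share = 0.05, horizon = 5,
                                       min_deaths = 50) {
  stopifnot(inherits(base_spec, "model_spec"))
  if (!length(candidates)) return(base_spec)
  added <- character()
  rows <- list()
  for (cand in candidates) {
    spec_minus <- model_spec(base_spec$sex,
                             factors = union(base_spec$factors,
                                             setdiff(candidates, cand)),
                             interactions = base_spec$interactions)
    alg <- extract_algorithm(fit_hazard_model(coded, spec_minus, min_deaths))
    cal <- subgroup_calibration(coded, alg, subgroups, horizon = horizon)
    eligible <- !is.na(cal$death_share) & cal$death_share > min_death_share
    breach <- eligible & !is.na(cal$pct_diff) & abs(cal$pct_diff) > threshold
    if (any(breach)) added <- c(added, cand)
    rows[[cand]] <- data.frame(candidate = cand, added = any(breach),
                               worst = max(abs(cal$pct_diff[eligible]),
                                           na.rm = TRUE))
  }
  out <- model_spec(base_spec$sex,
                    factors = union(base_spec$factors, added),
                    interactions = base_spec$interactions)
  attr(out, "assessment") <- do.call(rbind, rows)
  out
}

#' Variance-inflation report for a model specification
#'
#' Reports the variance inflation factor of each design column (1 / (1 - R^2)
#' from regressing the column on the others); values above 10 are flagged as
#' collinear.
#'
#' @inheritParams fit_hazard_model
#' @return data.frame with `term`, `vif`, `flag`.
#' @export
vif_report <- function(coded, spec) {
  X <- exposure_design(coded[coded$sex == spec$sex, , drop = FALSE], spec)
  keep <- apply(X, 2, stats::sd) > 0
  vif <- rep(NA_real_, ncol(X))
  if (sum(keep) >= 2) {
    ci <- tryCatch(solve(stats::cor(X[, keep, drop = FALSE])),
                   error = function(e) NULL)
    if (!is.null(ci)) vif[keep] <- diag(ci)
  }
  data.frame(term = colnames(X), vif = vif,
             flag = !is.na(vif) & vif > 10)
}

#' Extract a self-contained risk algorithm from a fitted hazard model
#'
#' Packages the fitted log-hazard-ratio coefficients, their covariance, the
#' model specification, and the baseline survival curve (Breslow estimator at
#' the reference covariate pattern, evaluated on an integer age grid) into a
#' serializable risk algorithm that predicts independently of the training
#' data. Calibration factors are initialized to 1 on the life-table age bins.
#'
#' @param fitted a `hazard_fit`.
#' @param grid_max upper end of the integer age grid (default 105, so that
#'   5-year risks can be formed for entry ages up to 100).
#' @return object of class `risk_algorithm`.
#' @export
extract_algorithm <- function(fitted, grid_max = 105) {
  stopifnot(inherits(fitted, "hazard_fit"))
  bh <- survival::basehaz(fitted$fit, centered = FALSE)
  grid <- 20:grid_max
  # step-function cumulative hazard at the reference pattern, by age
  idx <- findInterval(grid, bh$time)
  H0 <- cummax(c(0, bh$hazard)[idx + 1L])
  cal <- age_bins_5y()
  cal$factor <- 1
  structure(list(sex = fitted$spec$sex, coef = fitted$coef,
                 vcov = fitted$vcov, spec = fitted$spec,
                 baseline_age = grid, baseline_cumhaz = H0,
                 baseline_s0 = exp(-H0),
                 calibration = cal,
                 n = fitted$n, deaths = fitted$deaths),
            class = "risk_algorithm")
}

#' @export
print.risk_algorithm <- function(x, ...) {
  cat("Risk algorithm (", x$sex, "): ", length(x$coef), " terms, baseline on ",
      "ages ", min(x$baseline_age), "-", max(x$baseline_age), "\n", sep = "")
  cal <- x$calibration
  if (any(cal$factor != 1)) cat("calibrated: factors ",
                                round(min(cal$factor), 3), "-",
                                round(max(cal$factor), 3), "\n", sep = "")
  invisible(x)
}
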