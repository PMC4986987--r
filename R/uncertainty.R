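#' Bootstrap configuration for burden uncertainty
#'
#' @param B number of replicates (default 500).
#' @param seed integer seed.
#' @param sources uncertainty sources to combine: `"coefficients"` (risk
#'   model parameters, drawn multivariate-normal at the estimates with the
#'   fitted covariance) and/or `"survey"` (with-replacement respondent
#'   resampling with rescaled weights, approximating survey exposure
#'   variability). An empty vector collapses the interval onto the point
#'   estimate.
#' @param level confidence level for the percentile intervals.
#' @return object of class `bootstrap_config`.
#' @export
bootstrap_config <- function(B = 500, seed = 1,
                             sources = c("coefficients", "survey"),
                             level = 0.95) {
  stopifnot(B >= 2, level > 0, level < 1)
  bad <- setdiff(sources, c("coefficients", "survey"))
  if (length(bad)) stop("unknown sources: ", paste(bad, collapse = ", "))
  structure(list(B = B, seed = seed, sources = sources, level = level),
            class = "bootstrap_config")
}

perturb_coefficients <- function(alg) {
  alg$coef[] <- MASS::mvrnorm(1, mu = alg$coef, Sigma = alg$vcov)
  alg
}

#' Bootstrap confidence intervals for burden estimates
#'
#' Two-source bootstrap for out-of-sample prediction with a population health
#' survey: each replicate (i) redraws the algorithm coefficients from a
#' multivariate normal at the estimates with the fitted covariance, and (ii)
#' resamples survey respondents with replacement within sex, rescaling
#' weights to preserve the represented population. When an observed rate
#' table is supplied, each replicate is recalibrated against it, so the
#' intervals propagate coefficient and exposure uncertainty through the
#' calibration step exactly as the point estimate does. Percentile intervals
#' are reported per burden quantity; the point estimate is included in the
#' replicate pool so it always lies inside its own interval.
#'
#' @param algorithms per-sex `risk_algorithm` list.
#' @param survey respondent or coded table.
#' @param behaviours behaviours to delete.
#' @param config a [bootstrap_config()].
#' @param observed_rates optional observed age-sex rate table; replicates
#'   (and the point estimate) are recalibrated against it.
#' @return the point-estimate [burden_estimate()] with `<quantity>_lo` and
#'   `<quantity>_hi` columns appended; attribute `"replicates"` holds the
#'   per-replicate draws.
#' @export
bootstrap_burden <- function(algorithms, survey,
                             behaviours = behaviour_groups(),
                             config = bootstrap_config(),
                             observed_rates = NULL) {
  stopifnot(inherits(config, "bootstrap_config"))
  coded <- if (!is.null(survey$smoking_class)) survey
           else code_exposures(survey)
  sexes <- intersect(c("male", "female"), unique(as.character(coded$sex)))
  algs <- lapply(sexes, function(s) get_algorithm(algorithms, s))
  names(algs) <- sexes

  use_coef <- "coefficients" %in% config$sources
  if (use_coef) {
    ok <- vapply(algs, function(a) {
      !is.null(a$vcov) &&
        !inherits(try(chol(a$vcov), silent = TRUE), "try-error")
    }, logical(1))
    if (!all(ok)) {
      warning("degenerate or missing coefficient covariance; ",
              "falling back to survey-only resampling")
      use_coef <- FALSE
    }
  }
  use_survey <- "survey" %in% config$sources

  calibrated <- function(as_) {
    if (is.null(observed_rates)) return(as_)
    lapply(as_, function(a)
      recalibrate(a, coded[coded$sex == a$sex, , drop = FALSE],
                  observed_rates))
  }
  point <- burden_estimate(calibrated(algs), coded, behaviours)

  quantities <- c("baseline_deaths", "reference_deaths",
                  "attributable_deaths", "attributable_fraction",
                  "baseline_le", "reference_le", "le_lost")
  set.seed(config$seed)
  reps <- vector("list", config$B)
  for (b in seq_len(config$B)) {
    ab <- algs
    if (use_coef) ab <- lapply(ab, perturb_coefficients)
    db <- coded
    if (use_survey) {
      parts <- lapply(sexes, function(s) {
        rows <- which(coded$sex == s)
        i <- sample(rows, length(rows), replace = TRUE)
        d <- coded[i, , drop = FALSE]
        d$weight <- d$weight * sum(coded$weight[rows]) / sum(d$weight)
        d
      })
      db <- do.call(rbind, parts)
    }
    if (!is.null(observed_rates))
      ab <- lapply(ab, function(a)
        recalibrate(a, db[db$sex == a$sex, , drop = FALSE], observed_rates))
    est <- burden_estimate(ab, db, behaviours)
    reps[[b]] <- est[, c("sex", quantities)]
  }
  repdf <- do.call(rbind, reps)

  al <- (1 - config$level) / 2
  for (qn in quantities) {
    point[[paste0(qn, "_lo")]] <- NA_real_
    point[[paste0(qn, "_hi")]] <- NA_real_
    for (k in seq_len(nrow(point))) {
      s <- point$sex[k]
      draws <- c(point[[qn]][k], repdf[[qn]][repdf$sex == s])
      ci <- stats::quantile(draws, c(al, 1 - al), names = FALSE)
      point[[paste0(qn, "_lo")]][k] <- ci[1]
      point[[paste0(qn, "_hi")]][k] <- ci[2]
    }
  }
  attr(point, "replicates") <- repdf
  attr(point, "sources") <- c(if (use_coef) "coefficients",
                              if (use_survey) "survey")
  point
}
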