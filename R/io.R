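survey_logical_cols <- function() {
  c("lifetime_cigs_lt_100", "weekly_binge", "heart_disease", "stroke",
    "cancer", "diabetes", "bmi_ge_35", "died")
}

#' Read a respondent survey table from CSV
#'
#' Parses the documented survey schema (see the packaged data dictionary,
#' `system.file("extdata", "data_dictionary.csv", package = "mortburden")`).
#' Unknown columns are preserved but ignored; missing values are empty cells.
#' Rows failing basic validation (age outside 20-99, non-positive weight,
#' negative counts) are excluded and logged in the `"validation"` attribute
#' with their file row numbers.
#'
#' @param path CSV file path.
#' @return respondent data.frame; attribute `"validation"` is a data.frame
#'   of (row, id, reason) for excluded rows.
#' @export
read_survey <- function(path) {
  r <- utils::read.csv(path, stringsAsFactors = FALSE)
  mandatory <- unlist(respondent_required_fields(), use.names = FALSE)
  miss <- setdiff(mandatory, names(r))
  if (length(miss))
    stop("missing column: ", paste(miss, collapse = ", "))
  for (cl in intersect(survey_logical_cols(), names(r)))
    r[[cl]] <- as.logical(r[[cl]])
  if (is.null(r$id)) r$id <- seq_len(nrow(r))

  reason <- rep(NA_character_, nrow(r))
  bad_age <- !is.na(r$age) & (r$age < 20 | r$age > 99)
  reason[bad_age] <- "invalid:age"
  bad_w <- is.na(reason) & !is.na(r$weight) & r$weight <= 0
  reason[bad_w] <- "invalid:weight"
  for (cl in c("drinks_last_week", "max_drinks_any_day_last_week",
               "cigs_per_day")) {
    if (is.null(r[[cl]])) next
    bad <- is.na(reason) & !is.na(r[[cl]]) & r[[cl]] < 0
    reason[bad] <- paste0("invalid:", cl)
  }
  keep <- is.na(reason)
  out <- r[keep, , drop = FALSE]
  rownames(out) <- NULL
  excl <- data.frame(row = which(!keep) + 1L,  # +1 for the header line
                     id = r$id[!keep], reason = reason[!keep])
  if (nrow(excl))
    message("read_survey: excluded ", nrow(excl), " row(s): ",
            paste(unique(excl$reason), collapse = ", "))
  attr(out, "validation") <- excl
  out
}

#' Write a respondent survey table to CSV
#'
#' @param survey respondent data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_survey <- function(survey, path) {
  utils::write.csv(survey, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Serialize a risk algorithm to JSON
#'
#' Writes a self-contained structured-text representation (schema version,
#' sex, model specification, coefficients, coefficient covariance, baseline
#' survival grid, calibration table) at full numeric precision, so that a
#' round trip through [read_algorithm()] reproduces predictions exactly.
#'
#' @param algorithm a `risk_algorithm`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_algorithm <- function(algorithm, path) {
  stopifnot(inherits(algorithm, "risk_algorithm"))
  x <- list(
    schema = "mortburden-risk-algorithm/1",
    sex = algorithm$sex,
    spec = list(factors = algorithm$spec$factors,
                interactions = algorithm$spec$interactions),
    terms = names(algorithm$coef),
    coef = unname(algorithm$coef),
    vcov = algorithm$vcov,
    baseline_age = algorithm$baseline_age,
    baseline_cumhaz = if (!is.null(algorithm$baseline_cumhaz))
      algorithm$baseline_cumhaz else -log(algorithm$baseline_s0),
    calibration = algorithm$calibration,
    n = algorithm$n, deaths = algorithm$deaths
  )
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' Read a risk algorithm from JSON
#'
#' @param path file written by [write_algorithm()].
#' @return a `risk_algorithm`.
#' @export
read_algorithm <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(x$schema, "mortburden-risk-algorithm/1"))
    stop("unrecognized algorithm schema: ", x$schema)
  coef <- stats::setNames(x$coef, x$terms)
  vcov <- NULL
  if (!is.null(x$vcov)) {
    vcov <- matrix(unlist(x$vcov), nrow = length(coef), byrow = TRUE,
                   dimnames = list(x$terms, x$terms))
  }
  structure(list(sex = x$sex, coef = coef, vcov = vcov,
                 spec = model_spec(x$sex, factors = x$spec$factors,
                                   interactions = as.character(x$spec$interactions)),
                 baseline_age = x$baseline_age,
                 baseline_cumhaz = x$baseline_cumhaz,
                 baseline_s0 = exp(-x$baseline_cumhaz),
                 calibration = as.data.frame(x$calibration),
                 n = x$n, deaths = x$deaths),
            class = "risk_algorithm")
}

#' Write the ground-truth sidecar for a synthetic cohort
#'
#' Structured-text record of the generating parameters (true log hazard
#' ratios, Gompertz baseline, seed, sizes) for downstream recovery tests.
#'
#' @param config a [cohort_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(config, path) {
  stopifnot(inherits(config, "cohort_config"))
  jsonlite::write_json(
    list(schema = "mortburden-truth/1",
         n = config$n, seed = config$seed, sex_split = config$sex_split,
         horizon = config$horizon, latent_rho = config$latent_rho,
         baseline = config$baseline,
         true_log_hr = as.list(config$true_log_hr)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' End-to-end pipeline configuration
#'
#' @param out_dir output directory (created if needed).
#' @param seed integer seed driving every random stage.
#' @param survey path to a survey CSV, a respondent data.frame, or `NULL` to
#'   simulate a synthetic survey of `synthetic_n` respondents.
#' @param algorithm path to an algorithm JSON, a per-sex algorithm list, or
#'   `NULL` to derive algorithms from the (linked) survey.
#' @param observed_rates path/data.frame of observed age-sex rates, or
#'   `NULL`; for a synthetic survey, `NULL` defaults to the generator's truth
#'   table so the calibration stage is exercised.
#' @param behaviours behaviours to delete in the burden stage.
#' @param group_by optional grouping column for an equity table.
#' @param bootstrap_B bootstrap replicates (0 disables the bootstrap stage).
#' @param synthetic_n size of the simulated survey when `survey` is `NULL`.
#' @return list of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1, survey = NULL, algorithm = NULL,
                       observed_rates = NULL,
                       behaviours = behaviour_groups(), group_by = NULL,
                       bootstrap_B = 0, synthetic_n = 20000) {
  structure(list(out_dir = out_dir, seed = seed, survey = survey,
                 algorithm = algorithm, observed_rates = observed_rates,
                 behaviours = behaviours, group_by = group_by,
                 bootstrap_B = bootstrap_B, synthetic_n = synthetic_n),
            class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full derivation-validation-application pipeline
#'
#' Orchestrates the three uses of a mortality risk algorithm: derivation
#' (fit sex-specific hazard models when the survey carries follow-up),
#' validation (concordance, percentile ratio, decile calibration),
#' recalibration to observed rates, and application (life tables, burden,
#' optional equity table and bootstrap intervals). Writes CSV outputs plus a
#' provenance manifest (input hashes, configuration, package version) to
#' `config$out_dir`. Deterministic given `config$seed`.
#'
#' @param config a [run_config()].
#' @return named list of output file paths, invisibly; the manifest path is
#'   included.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character()
  hashes <- list()
  emit <- function(name, df) {
    p <- file.path(config$out_dir, paste0(name, ".csv"))
    utils::write.csv(df, p, row.names = FALSE, na = "")
    outputs[[name]] <<- p
    p
  }

  synth_cfg <- NULL
  survey <- stage("survey", {
    if (is.null(config$survey)) {
      synth_cfg <- cohort_config(n = config$synthetic_n, seed = config$seed)
      simulate_followup(generate_cohort(synth_cfg), synth_cfg)
    } else if (is.character(config$survey)) {
      hashes$survey <- unname(tools::md5sum(config$survey))
      read_survey(config$survey)
    } else config$survey
  })
  coded <- stage("coding", code_exposures(survey))

  linked <- !is.null(coded$followup_years) && !is.null(coded$died)
  algorithms <- stage("derivation", {
    if (is.null(config$algorithm)) {
      if (!linked) stop("no algorithm supplied and survey is unlinked")
      sexes <- intersect(c("male", "female"), unique(as.character(coded$sex)))
      algs <- lapply(sexes, function(s)
        extract_algorithm(fit_hazard_model(coded, model_spec(s))))
      stats::setNames(algs, sexes)
    } else if (is.character(config$algorithm)) {
      hashes$algorithm <- unname(tools::md5sum(config$algorithm))
      a <- read_algorithm(config$algorithm)
      stats::setNames(list(a), a$sex)
    } else config$algorithm
  })
  for (s in names(algorithms))
    write_algorithm(algorithms[[s]],
                    outputs[[paste0("algorithm_", s)]] <-
                      file.path(config$out_dir, paste0("algorithm_", s, ".json")))

  if (linked) {
    val <- stage("validation", {
      rows <- lapply(names(algorithms), function(s) {
        v <- validate_algorithm(coded, algorithms[[s]], ci_boot = 0)
        data.frame(sex = s, c_statistic = v$c_statistic,
                   ratio_90_10 = v$ratio_90_10)
      })
      do.call(rbind, rows)
    })
    emit("validation", val)
  }

  observed <- stage("observed_rates", {
    if (is.character(config$observed_rates)) {
      hashes$observed_rates <- unname(tools::md5sum(config$observed_rates))
      utils::read.csv(config$observed_rates, stringsAsFactors = FALSE)
    } else if (is.null(config$observed_rates) && !is.null(synth_cfg)) {
      observed_rate_table(synth_cfg, n = min(2e5, 10 * config$synthetic_n))
    } else config$observed_rates
  })
  if (!is.null(observed)) {
    algorithms <- stage("calibration", lapply(algorithms, function(a)
      recalibrate(a, coded[coded$sex == a$sex, , drop = FALSE], observed)))
    emit("observed_rates", observed)
  }

  stage("lifetable", for (s in names(algorithms)) {
    d <- coded[coded$sex == s, , drop = FALSE]
    q1 <- predict_risk(algorithms[[s]], d, 1)
    lt <- build_life_table(aggregate_interval_q(q1, d$age, d$weight))
    lv <- le_variance(lt)
    tab <- as.data.frame(lt)
    tab$se_e <- c(lv$se, rep(NA, nrow(tab) - 1))
    emit(paste0("life_table_", s), tab)
  })

  burden <- stage("burden", {
    if (config$bootstrap_B > 0)
      bootstrap_burden(algorithms, coded, config$behaviours,
                       bootstrap_config(B = config$bootstrap_B,
                                        seed = config$seed),
                       observed_rates = observed)
    else burden_estimate(algorithms, coded, config$behaviours)
  })
  emit("burden", as.data.frame(burden))

  if (!is.null(config$group_by))
    emit(paste0("equity_", config$group_by),
         stage("equity", equity_table(algorithms, coded, config$group_by,
                                      config$behaviours)))

  manifest <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(
    list(package = "mortburden",
         version = as.character(utils::packageVersion("mortburden")),
         seed = config$seed,
         behaviours = config$behaviours,
         input_hashes = hashes,
         output_hashes = as.list(tools::md5sum(unlist(outputs))),
         outputs = as.list(outputs)),
    manifest, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  outputs[["manifest"]] <- manifest
  invisible(outputs)
}
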