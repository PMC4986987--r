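#' Concordance index for left-truncated survival on the age scale
#'
#' Probability that, of two comparable respondents, the one with higher
#' predicted risk dies first. With delayed entry, a pair is comparable at a
#' death age `t` only if the comparator was under observation at `t`
#' (entered before `t` and exited later, or exited at `t` alive). Risk ties
#' count one half. Pairs of deaths at the same age are not comparable.
#'
#' @param risk predicted risks.
#' @param entry,exit entry and exit ages; `exit > entry` required.
#' @param died logical event indicator.
#' @param ci_boot number of respondent bootstrap resamples for a percentile
#'   confidence interval (0 to skip).
#' @param level confidence level.
#' @return list with `c`, `concordant` (weighted count), `comparable`
#'   (pair count), and `ci` when requested.
#' @export
concordance_index <- function(risk, entry, exit, died, ci_boot = 0,
                              level = 0.95) {
  if (any(exit <= entry)) stop("exit must exceed entry for all respondents")
  point <- function(risk, entry, exit, died) {
    conc <- 0
    comp <- 0
    for (i in which(died)) {
      t <- exit[i]
      at_risk <- entry < t & (exit > t | (exit == t & !died))
      at_risk[i] <- FALSE
      m <- sum(at_risk)
      if (!m) next
      comp <- comp + m
      conc <- conc + sum(risk[i] > risk[at_risk]) +
        0.5 * sum(risk[i] == risk[at_risk])
    }
    list(conc = conc, comp = comp)
  }
  p <- point(risk, entry, exit, died)
  if (p$comp == 0) stop("no comparable pairs")
  out <- list(c = p$conc / p$comp, concordant = p$conc, comparable = p$comp)
  if (ci_boot > 0) {
    n <- length(risk)
    reps <- vapply(seq_len(ci_boot), function(b) {
      i <- sample.int(n, n, replace = TRUE)
      pb <- point(risk[i], entry[i], exit[i], died[i])
      if (pb$comp == 0) NA_real_ else pb$conc / pb$comp
    }, numeric(1))
    al <- (1 - level) / 2
    out$ci <- stats::quantile(reps, c(al, 1 - al), na.rm = TRUE, names = FALSE)
  }
  out
}

#' 90:10 risk percentile ratio
#'
#' Mean predicted risk of the top decile divided by the mean of the bottom
#' decile — a discrimination summary robust to the censoring structure.
#'
#' @param risk at least 10 predicted risks; the bottom-decile mean must be
#'   positive.
#' @return scalar ratio.
#' @export
percentile_ratio <- function(risk) {
  n <- length(risk)
  if (n < 10) stop("need at least 10 risks")
  k <- floor(n / 10)
  s <- sort(risk)
  bottom <- mean(s[seq_len(k)])
  if (bottom <= 0) stop("bottom-decile mean risk is zero")
  mean(s[seq.int(n - k + 1, n)]) / bottom
}

# administrative-censoring-aware observed vs predicted deaths for one subset
observed_vs_predicted <- function(coded, risk_h, horizon, sel) {
  # eligible: died within horizon, or had at least `horizon` potential
  # follow-up (so their horizon outcome is fully observed)
  eligible <- sel & (coded$followup_years >= horizon |
                       (coded$died & coded$followup_years <= horizon))
  obs <- sum(coded$died[eligible] & coded$followup_years[eligible] <= horizon)
  pred <- sum(risk_h[eligible])
  c(n = sum(eligible), observed = obs, predicted = pred)
}

#' Subgroup and risk-decile calibration of a risk algorithm
#'
#' For each subgroup: observed deaths within the horizon (among respondents
#' whose horizon outcome is fully observed, i.e. death within the horizon or
#' at least that much follow-up), the sum of predicted risks, the relative
#' predicted-observed difference, and a flag when it exceeds 20%. A
#' risk-decile calibration table over the whole cohort is attached as
#' attribute `"deciles"`.
#'
#' @param coded coded exposure table with follow-up (one sex).
#' @param algorithm the `risk_algorithm` to assess.
#' @param subgroups named list of functions `f(coded) -> logical`.
#' @param horizon risk horizon in years.
#' @param flag_threshold relative difference considered clinically important.
#' @return data.frame with one row per subgroup: `subgroup`, `n`, `observed`,
#'   `predicted`, `death_share`, `pct_diff`, `flag`,
#'   `undefined` (no observed deaths).
#' @export
subgroup_calibration <- function(coded, algorithm, subgroups, horizon = 5,
                                 flag_threshold = 0.20) {
  if (is.null(coded$followup_years) || is.null(coded$died))
    stop("subgroup calibration needs follow-up data")
  coded <- coded[coded$sex == algorithm$sex, , drop = FALSE]
  risk_h <- predict_risk(algorithm, coded, horizon)
  total_obs <- observed_vs_predicted(coded, risk_h, horizon,
                                     rep(TRUE, nrow(coded)))[["observed"]]

  one <- function(sel, name) {
    v <- observed_vs_predicted(coded, risk_h, horizon, sel)
    undef <- v[["observed"]] == 0
    pd <- if (undef) NA_real_ else
      (v[["predicted"]] - v[["observed"]]) / v[["observed"]]
    data.frame(subgroup = name, n = v[["n"]], observed = v[["observed"]],
               predicted = v[["predicted"]],
               death_share = if (total_obs > 0) v[["observed"]] / total_obs
                             else NA_real_,
               pct_diff = pd,
               flag = !is.na(pd) && abs(pd) > flag_threshold,
               undefined = undef)
  }
  rows <- mapply(function(f, nm) one(f(coded), nm), subgroups,
                 names(subgroups), SIMPLIFY = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL

  dec <- cut(rank(risk_h, ties.method = "first"),
             breaks = seq(0, nrow(coded), length.out = 11),
             labels = FALSE, include.lowest = TRUE)
  decile_rows <- lapply(1:10, function(k) one(dec == k, paste0("decile_", k)))
  attr(out, "deciles") <- do.call(rbind, decile_rows)
  out
}

#' Validate a risk algorithm on a linked cohort
#'
#' Combines discrimination (concordance with left truncation, 90:10
#' percentile ratio) and subgroup calibration into one report.
#'
#' @inheritParams subgroup_calibration
#' @param ci_boot bootstrap resamples for the concordance confidence
#'   interval (default 200).
#' @return list of class `validation_report` with elements `c_statistic`,
#'   `ci`, `ratio_90_10`, and `subgroups`.
#' @export
validate_algorithm <- function(coded, algorithm, subgroups = NULL,
                               horizon = 5, ci_boot = 200) {
  coded <- coded[coded$sex == algorithm$sex, , drop = FALSE]
  risk <- predict_risk(algorithm, coded, horizon)
  # follow-up time scale: all respondents enter at 0, so age differences
  # contribute to discrimination, matching how the C-statistic is
  # conventionally reported for these algorithms
  cc <- concordance_index(risk, rep(0, nrow(coded)),
                          pmax(coded$followup_years, 1 / 365.25),
                          coded$died, ci_boot = ci_boot)
  sub <- if (!is.null(subgroups))
    subgroup_calibration(coded, algorithm, subgroups, horizon) else NULL
  ratio <- tryCatch(percentile_ratio(risk), error = function(e) {
    warning("90:10 ratio undefined: ", conditionMessage(e))
    NA_real_
  })
  structure(list(c_statistic = cc$c, ci = cc$ci,
                 ratio_90_10 = ratio, subgroups = sub),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("C-statistic:", round(x$c_statistic, 3))
  if (!is.null(x$ci)) cat(" [", round(x$ci[1], 3), "-", round(x$ci[2], 3), "]")
  cat("\n90:10 percentile ratio:", round(x$ratio_90_10, 2), "\n")
  if (!is.null(x$subgroups)) {
    cat("subgroups flagged (>20%):", sum(x$subgroups$flag), "of",
        nrow(x$subgroups), "\n")
  }
  invisible(x)
}
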