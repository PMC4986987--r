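#' Aggregate individual annual risks into 5-year interval death probabilities
#'
#' For each life-table interval [x, x+5) the survey-weighted mean annual death
#' risk `qbar` of respondents aged in the interval is converted to the
#' interval death probability `q = 1 - (1 - qbar)^5` (annual risk assumed
#' constant within the interval). The variance of `q` is propagated from the
#' variance of the weighted mean by the delta method. Intervals containing no
#' respondents are filled by log-linear interpolation (log-linear
#' extrapolation at the edges) over interval midpoints and flagged.
#'
#' @param annual_risk per-respondent annual death probabilities.
#' @param age respondent ages (20 to 99).
#' @param weight positive survey weights.
#' @return data.frame with one row per interval: `age_lo`, `age_hi`, `q`,
#'   `var_q`, `n` (respondents contributing), `interpolated`.
#' @export
aggregate_interval_q <- function(annual_risk, age, weight) {
  if (any(weight <= 0)) stop("weights must be positive")
  if (any(age < 20 | age >= 100)) stop("ages must be in [20, 100)")
  if (any(annual_risk < 0 | annual_risk > 1)) stop("risks must be in [0, 1]")
  idx <- age_bin_index(age)
  bins <- age_bins_5y()
  nb <- nrow(bins)
  qbar <- vbar <- rep(NA_real_, nb)
  cnt <- integer(nb)
  for (j in seq_len(nb)) {
    i <- which(idx == j)
    cnt[j] <- length(i)
    if (!length(i)) next
    w <- weight[i]
    qbar[j] <- sum(w * annual_risk[i]) / sum(w)
    vbar[j] <- sum(w^2 * (annual_risk[i] - qbar[j])^2) / sum(w)^2
  }
  empty <- is.na(qbar)
  if (all(empty)) stop("no respondents in any life-table interval")
  if (any(empty)) {
    src <- which(!empty & qbar > 0)
    mid <- bins$age_lo + 2.5
    if (length(src) >= 2) {
      fit_y <- log(qbar[src])
      fill <- stats::approx(mid[src], fit_y, xout = mid[empty], rule = 1)$y
      # log-linear extrapolation from the two nearest source bins
      lo2 <- utils::head(src, 2); hi2 <- utils::tail(src, 2)
      slope_lo <- diff(fit_y[1:2]) / diff(mid[lo2])
      slope_hi <- diff(fit_y[c(length(src) - 1, length(src))]) / diff(mid[hi2])
      below <- mid[empty] < mid[src[1]]
      above <- mid[empty] > mid[src[length(src)]]
      fill[below] <- fit_y[1] + slope_lo * (mid[empty][below] - mid[src[1]])
      fill[above] <- fit_y[length(src)] +
        slope_hi * (mid[empty][above] - mid[src[length(src)]])
      qbar[empty] <- exp(fill)
    } else if (length(src) == 1) {
      qbar[empty] <- qbar[src]
    } else {
      qbar[empty] <- 0
    }
    vbar[empty] <- 0
    message("life table: filled ", sum(empty), " empty interval(s) [",
            paste(bins$age_lo[empty], collapse = ", "), "] by interpolation")
  }
  qbar <- pmin(qbar, 1)
  data.frame(age_lo = bins$age_lo, age_hi = bins$age_hi,
             q = 1 - (1 - qbar)^5,
             var_q = (5 * (1 - qbar)^4)^2 * vbar,
             n = cnt, interpolated = empty)
}

#' Build an abridged period life table from interval death probabilities
#'
#' Standard abridged construction on the sixteen 5-year intervals
#' [20,25) ... [95,100): survivors `l` from a radix of 100,000, person-years
#' `L = 5 l_{x+5} + a d` with `a = 2.5` years lived on average by interval
#' decedents, cumulative person-years `T`, and remaining life expectancy
#' `e = T / l`. The terminal interval [95,100) is closed with `q = 1`.
#'
#' @param q numeric vector of 16 interval death probabilities, or the
#'   data.frame returned by [aggregate_interval_q()] (whose `var_q` is then
#'   carried through to [le_variance()]).
#' @param var_q optional vector of interval death-probability variances.
#' @return data.frame of class `life_table` with columns `age_lo`, `age_hi`,
#'   `q`, `var_q`, `l`, `d`, `L`, `T`, `e`.
#' @export
build_life_table <- function(q, var_q = NULL) {
  if (is.data.frame(q)) {
    if (is.null(var_q)) var_q <- q$var_q
    q <- q$q
  }
  bins <- age_bins_5y()
  nb <- nrow(bins)
  if (length(q) != nb) stop("need ", nb, " interval death probabilities")
  if (any(is.na(q)) || any(q < 0 | q > 1)) stop("q must be within [0, 1]")
  if (is.null(var_q)) var_q <- rep(0, nb)
  if (any(var_q < 0)) stop("var_q must be non-negative")
  q[nb] <- 1
  var_q[nb] <- 0

  radix <- 1e5
  a <- 2.5
  width <- 5
  l <- numeric(nb)
  l[1] <- radix
  for (j in seq_len(nb - 1)) l[j + 1] <- l[j] * (1 - q[j])
  d <- l * q
  l_next <- c(l[-1], 0)
  L <- width * l_next + a * d
  Tx <- rev(cumsum(rev(L)))
  e <- ifelse(l > 0, Tx / l, 0)

  out <- data.frame(age_lo = bins$age_lo, age_hi = bins$age_hi,
                    q = q, var_q = var_q, l = l, d = d, L = L, T = Tx, e = e)
  class(out) <- c("life_table", "data.frame")
  out
}

#' Life expectancy from a life table, on the full lifespan scale
#'
#' Remaining life expectancy at age 20 plus 20, i.e. the expected age at
#' death for the stationary population entering the table, matching how
#' period life expectancy is conventionally reported.
#'
#' @param lt a `life_table`.
#' @return scalar, years.
#' @export
life_expectancy <- function(lt) {
  stopifnot(inherits(lt, "life_table"))
  20 + lt$e[1]
}

#' Variance and confidence interval for life expectancy
#'
#' Delta-method propagation of the interval death-probability variances to
#' the life expectancy at age 20 (Chiang's method): each interval contributes
#' `l_x^2 * ((1 - a/n) n + e_{x+n})^2 * Var(q_x)`, summed and divided by
#' `l_20^2`. The terminal interval, whose `q` is fixed at 1, contributes
#' nothing.
#'
#' @param lt a `life_table` carrying `var_q`.
#' @param level confidence level (default 0.95).
#' @return list with `var`, `se`, and `ci` (bounds for the full-scale life
#'   expectancy, [life_expectancy()]).
#' @export
le_variance <- function(lt, level = 0.95) {
  stopifnot(inherits(lt, "life_table"))
  nb <- nrow(lt)
  a_frac <- 2.5 / 5
  e_next <- c(lt$e[-1], 0)
  contrib <- lt$l^2 * ((1 - a_frac) * 5 + e_next)^2 * lt$var_q
  contrib[nb] <- 0
  v <- sum(contrib) / lt$l[1]^2
  se <- sqrt(v)
  zc <- stats::qnorm(1 - (1 - level) / 2)
  le <- life_expectancy(lt)
  list(var = v, se = se, ci = c(lower = le - zc * se, upper = le + zc * se))
}
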