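test_that("zero linear predictor reduces risk to the baseline", {
  alg <- constant_hazard_algorithm(lambda = 0.02)
  r <- code_exposures(make_respondent(age = 60))  # non-smoker: LP = 0
  expect_equal(predict_risk(alg, r, 1), 1 - exp(-0.02))
  expect_equal(predict_risk(alg, r, 5), 1 - exp(-0.1))
})

test_that("risk ratio approaches the hazard ratio as baseline risk vanishes", {
  hr <- 2.83
  heavy <- code_exposures(make_respondent(age = 50,
                                          smoking_status = "current",
                                          cigs_per_day = 30))
  non <- code_exposures(make_respondent(age = 50))
  ratios <- sapply(c(1e-2, 1e-4, 1e-6), function(lambda) {
    alg <- constant_hazard_algorithm(lambda = lambda, heavy_log_hr = log(hr))
    predict_risk(alg, heavy, 5) / predict_risk(alg, non, 5)
  })
  expect_true(all(diff(abs(ratios - hr)) < 0))
  expect_equal(ratios[3], hr, tolerance = 1e-4)
})

test_that("longer horizons never lower risk and age limits are enforced", {
  coded <- fixture_coded()
  alg <- fixture_algorithms()$male
  m <- coded[coded$sex == "male", ]
  expect_true(all(predict_risk(alg, m, 5) >= predict_risk(alg, m, 1)))
  old <- m[1, ]; old$age <- 101
  expect_error(predict_risk(alg, old, 5), "age")
  expect_error(predict_risk(alg, m[1, ], 200), "age")
})

test_that("survey application reproduces row-wise prediction", {
  coded <- fixture_coded()[1:500, ]
  algs <- fixture_algorithms()
  out <- apply_to_survey(algs, coded)
  for (s in c("male", "female")) {
    i <- out$sex == s
    expect_equal(out$risk1[i], predict_risk(algs[[s]], coded[coded$sex == s, ], 1))
  }
  empty <- apply_to_survey(algs, coded[0, ])
  expect_equal(nrow(empty), 0)
  same <- coded[rep(1, 5), ]
  expect_equal(length(unique(apply_to_survey(algs, same)$risk5)), 1)
})

test_that("increasing a coefficient on a positive covariate raises risk", {
  alg <- fixture_algorithms()$male
  m <- fixture_coded()
  m <- m[m$sex == "male" & m$diet_score > 0, ][1:100, ]
  bumped <- alg
  bumped$coef["diet_score"] <- alg$coef["diet_score"] + 0.2
  expect_true(all(predict_risk(bumped, m, 5) >= predict_risk(alg, m, 5)))
})

test_that("recalibration reproduces the observed table exactly", {
  coded <- fixture_coded()
  alg <- fixture_algorithms()$male
  m <- coded[coded$sex == "male", ]
  m <- m[m$age < 85, ]  # keep inflated rates clear of the risk clamp at 1
  raw <- predict_risk(alg, m, 1)
  keep <- raw > 0   # bins need positive predicted risk for a defined factor
  m <- m[keep, ]; raw <- raw[keep]

  bins <- age_bins_5y()
  obs <- data.frame(sex = "male", bins, rate = NA_real_)
  for (j in seq_len(nrow(bins))) {
    i <- m$age >= bins$age_lo[j] & m$age <= bins$age_hi[j]
    obs$rate[j] <- if (any(i)) 1.2 * weighted.mean(raw[i], m$weight[i]) else 0
  }
  obs <- obs[obs$rate > 0, ]  # every occupied bin has positive rate
  cal <- recalibrate(alg, m, obs)
  expect_equal(unname(cal$calibration$factor), rep(1.2, nrow(obs)),
               tolerance = 1e-12)
  q1 <- predict_risk(cal, m, 1)
  for (j in seq_len(nrow(obs))) {
    i <- m$age >= obs$age_lo[j] & m$age <= obs$age_hi[j]
    expect_equal(weighted.mean(q1[i], m$weight[i]), obs$rate[j],
                 tolerance = 1e-12)
  }
  # idempotence
  cal2 <- recalibrate(cal, m, obs)
  expect_lt(max(abs(cal2$calibration$factor - cal$calibration$factor)), 1e-10)
})

test_that("an observed table equal to predictions leaves risks unchanged", {
  coded <- fixture_coded()
  alg <- fixture_algorithms()$female
  f <- coded[coded$sex == "female", ]
  raw <- predict_risk(alg, f, 1)
  keep <- raw > 0
  f <- f[keep, ]
  bins <- age_bins_5y()
  obs <- data.frame(sex = "female", bins, rate = NA_real_)
  raw <- raw[keep]
  for (j in seq_len(nrow(bins))) {
    i <- f$age >= bins$age_lo[j] & f$age <= bins$age_hi[j]
    obs$rate[j] <- if (any(i)) weighted.mean(raw[i], f$weight[i]) else NA
  }
  obs <- obs[!is.na(obs$rate) & obs$rate > 0, ]
  f <- f[f$age >= min(obs$age_lo) & f$age <= max(obs$age_hi), ]
  suppressWarnings(cal <- recalibrate(alg, f, obs))
  expect_equal(predict_risk(cal, f, 1), predict_risk(alg, f, 1),
               tolerance = 1e-10)
})

test_that("a missing observed bin is reported by name", {
  coded <- fixture_coded()
  alg <- fixture_algorithms()$male
  m <- coded[coded$sex == "male", ]
  obs <- fixture_observed()
  obs <- obs[!(obs$sex == "male" & obs$age_lo == 50), ]
  expect_error(recalibrate(alg, m, obs), "50")
})

test_that("recalibrated life expectancy matches the observed-rate table", {
  # when calibration bins coincide with the life-table bins, the weighted
  # predicted bin rates equal the observed rates, so the downstream life
  # table must reproduce the life expectancy implied by the observed rates
  coded <- fixture_coded()
  obs <- fixture_observed()
  alg <- fixture_algorithms()$male
  m <- coded[coded$sex == "male", ]
  m <- m[predict_risk(alg, m, 1) > 0, ]
  obsm <- obs[obs$sex == "male", ]
  suppressWarnings(cal <- recalibrate(alg, m, obsm))
  q1 <- predict_risk(cal, m, 1)
  le_pipeline <- life_expectancy(build_life_table(
    aggregate_interval_q(q1, m$age, m$weight)))

  occupied <- vapply(seq_len(nrow(obsm)), function(j)
    any(m$age >= obsm$age_lo[j] & m$age <= obsm$age_hi[j]), logical(1))
  q_obs <- 1 - (1 - obsm$rate)^5
  q_dir <- aggregate_interval_q(q1, m$age, m$weight)  # for interpolated bins
  q_obs[!occupied] <- q_dir$q[!occupied]
  le_direct <- life_expectancy(build_life_table(q_obs))
  expect_equal(le_pipeline, le_direct, tolerance = 0.05 / le_direct)
})

test_that("algorithm JSON round-trips with identical predictions", {
  alg <- fixture_algorithms()$male
  suppressWarnings(
    alg <- recalibrate(alg,
                       fixture_coded()[fixture_coded()$sex == "male", ],
                       fixture_observed()))
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  write_algorithm(alg, path)
  back <- read_algorithm(path)
  m <- fixture_coded()[fixture_coded()$sex == "male", ][1:200, ]
  expect_equal(predict_risk(back, m, 5), predict_risk(alg, m, 5),
               tolerance = 1e-12)
  expect_equal(back$coef, alg$coef)
  expect_equal(back$vcov, alg$vcov)
})
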