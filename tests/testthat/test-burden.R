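test_that("healthy-reference recoding touches only the listed behaviours", {
  coded <- fixture_coded()[1:500, ]
  cf <- healthy_reference(coded, c("smoking", "activity"))
  expect_true(all(cf$smoking_class == "non"))
  expect_true(all(cf$time_since_quit == 0))
  expect_true(all(cf$mets_per_day >= 3))
  expect_equal(cf$alcohol_class, coded$alcohol_class)
  expect_equal(cf$diet_score, coded$diet_score)
  expect_equal(cf$age, coded$age)
  expect_equal(cf$education, coded$education)

  # recoding is a no-op at the reference
  healthy <- code_exposures(make_respondent(mets_per_day = 4,
                                            fruit_veg_freq_per_day = 8,
                                            juice_freq_per_day = 0))
  expect_equal(healthy_reference(healthy, behaviour_groups()), healthy)
  # low activity raised exactly to the recommended 3 METs/day
  low <- code_exposures(make_respondent(mets_per_day = 1))
  expect_equal(healthy_reference(low, "activity")$mets_per_day, 3)
  expect_error(healthy_reference(coded, character()), "non-empty")
})

test_that("burden identities hold to machine precision", {
  coded <- fixture_coded()
  algs <- fixture_algorithms()
  be <- burden_estimate(algs, coded)
  expect_equal(be$attributable_deaths, be$baseline_deaths - be$reference_deaths)
  expect_equal(be$attributable_fraction,
               be$attributable_deaths / be$baseline_deaths)
  expect_equal(be$le_lost, be$reference_le - be$baseline_le)
  expect_true(all(be$attributable_deaths >= 0))
  expect_true(all(be$le_lost >= 0))
})

test_that("counterfactual risk never exceeds baseline under adverse coefficients", {
  # the guarantee holds when every deleted-behaviour coefficient points in
  # the unhealthy direction; zero out the time-since-quit credit (which can
  # make a long-quit former smoker's risk lower than a never-smoker's)
  coded <- fixture_coded()
  for (s in c("male", "female")) {
    alg <- fixture_algorithms()[[s]]
    alg$coef["time_since_quit"] <- 0
    alg$coef["alcohol_moderate"] <- max(0, alg$coef["alcohol_moderate"])
    d <- coded[coded$sex == s, ]
    cf <- healthy_reference(d, behaviour_groups())
    expect_true(all(predict_risk(alg, cf, 1) <=
                      predict_risk(alg, d, 1) + 1e-12))
  }
})

test_that("single-behaviour burden never exceeds the combined burden", {
  coded <- fixture_coded()
  algs <- fixture_algorithms()
  all4 <- burden_estimate(algs, coded)
  for (b in behaviour_groups()) {
    one <- burden_estimate(algs, coded, b)
    expect_true(all(one$attributable_deaths <= all4$attributable_deaths + 1e-9))
    expect_true(all(one$le_lost <= all4$le_lost + 1e-9))
  }
})

test_that("deleting an absent behaviour yields exactly zero burden", {
  coded <- fixture_coded()[1:800, ]
  coded$smoking_class[] <- "non"
  coded$time_since_quit <- 0
  be <- burden_estimate(fixture_algorithms(), coded, "smoking")
  expect_equal(be$attributable_deaths, rep(0, nrow(be)))
  expect_equal(be$le_lost, rep(0, nrow(be)))
})

test_that("burden recovery matches the generator's exact counterfactual", {
  cfg <- fixture_config()
  coded <- fixture_coded()
  obs <- fixture_observed()
  algs <- lapply(fixture_algorithms(), function(a)
    suppressWarnings(recalibrate(a, coded[coded$sex == a$sex, ], obs)))
  est <- burden_estimate(algs, coded)
  truth <- true_burden(cfg, n = 100000)
  for (s in c("male", "female")) {
    expect_equal(est$attributable_fraction[est$sex == s],
                 truth$attributable_fraction[truth$sex == s],
                 tolerance = 0.12)
    expect_equal(est$le_lost[est$sex == s],
                 truth$le_lost[truth$sex == s], tolerance = 0.15)
  }
})

test_that("profiles order life expectancy as expected", {
  coded <- fixture_coded()
  algs <- fixture_algorithms()
  healthy <- profile_life_expectancy(algs, coded, "healthy")
  unhealthy <- profile_life_expectancy(algs, coded, "unhealthy")
  expect_true(all(healthy$le > unhealthy$le))

  whole <- profile_life_expectancy(algs, coded,
                                   function(d) rep(TRUE, nrow(d)))
  be <- burden_estimate(algs, coded)
  expect_equal(whole$le, be$baseline_le)

  expect_error(profile_life_expectancy(algs, coded,
                                       function(d) rep(FALSE, nrow(d))),
               "match the profile")
})

test_that("fixed-vector mode with the reference vector gives baseline survival", {
  alg <- constant_hazard_algorithm(lambda = 0.01)
  ref <- code_exposures(make_respondent())
  got <- profile_life_expectancy(list(male = alg), NULL, ref)
  q1 <- 1 - exp(-0.01)
  expect_equal(got$le,
               life_expectancy(build_life_table(rep(1 - (1 - q1)^5, 16))))
})

test_that("equity rows satisfy the per-group identity and collapse property", {
  coded <- fixture_coded()
  algs <- fixture_algorithms()
  eq <- equity_table(algs, coded, "education", behaviours = "smoking")
  expect_equal(eq$le_lost, eq$reference_le - eq$baseline_le)
  expect_true(all(table(eq$sex) == 3))

  coded$one_group <- factor(rep("all", nrow(coded)))
  one <- equity_table(algs, coded, "one_group")
  overall <- burden_estimate(algs, coded)
  expect_equal(one$baseline_le, overall$baseline_le)
  expect_equal(one$attributable_fraction, overall$attributable_fraction)
})

test_that("smoking concentrated in low education shows there as lost years", {
  cfg <- cohort_config(n = 15000, seed = 313, latent_rho = 0.85)
  coded <- code_exposures(simulate_followup(generate_cohort(cfg), cfg))
  alg <- extract_algorithm(fit_hazard_model(coded, model_spec("male")))
  eq <- equity_table(list(male = alg), coded[coded$sex == "male", ],
                     "education", behaviours = "smoking")
  lt_hs <- eq$le_lost[eq$group == "lt_hs"]
  expect_gt(lt_hs, eq$le_lost[eq$group == "post_sec"])
  expect_equal(max(eq$le_lost), lt_hs)
})

test_that("the reporting identities reproduce printed-style summaries", {
  # feeding published-style components through the reporting formulas
  got <- burden_measures("male", baseline_deaths = 100,
                         reference_deaths = 72,
                         baseline_le = 79.3, reference_le = 82.4)
  expect_equal(got$le_lost, 3.1)
  expect_equal(got$attributable_fraction, 0.28)
})
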