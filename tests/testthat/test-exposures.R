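test_that("smoking coding follows the pack-a-day and lifetime rules", {
  out <- code_smoking(c("current", "never", "former", "former", "current"),
                      c(25, NA, 10, 22, NA),
                      c(FALSE, TRUE, FALSE, FALSE, FALSE),
                      c(NA, NA, 12, 3, NA))
  expect_equal(as.character(out$smoking_class),
               c("heavy", "non", "former_light", "former_heavy", "light"))
  expect_equal(out$time_since_quit, c(0, 0, 12, 3, 0))

  # former occasional smoker with <100 lifetime cigarettes is a non-smoker
  occ <- code_smoking("former", NA, TRUE, NA)
  expect_equal(as.character(occ$smoking_class), "non")
  expect_equal(occ$time_since_quit, 0)
})

test_that("smoking classes partition a status-by-consumption grid", {
  grid <- expand.grid(status = c("current", "former", "never"),
                      cigs = c(0, 1, 19, 20, 45),
                      lt100 = c(TRUE, FALSE),
                      tsq = c(0, 5, 30),
                      stringsAsFactors = FALSE)
  out <- code_smoking(grid$status, grid$cigs, grid$lt100, grid$tsq)
  expect_false(anyNA(out$smoking_class))
  expect_true(all(table(out$smoking_class) >= 0))
  # time since quit positive only for former classes
  former <- out$smoking_class %in% c("former_light", "former_heavy")
  expect_true(all(out$time_since_quit[!former] == 0))
})

test_that("alcohol coding matches the weekly, single-day, and binge cutoffs", {
  expect_equal(as.character(code_alcohol("male", 25, 4, FALSE)), "heavy")
  expect_equal(as.character(code_alcohol("female", 10, 3, FALSE)), "moderate")
  expect_equal(as.character(code_alcohol("male", 0, 0, FALSE)), "light_non")

  # boundary grid against the published cutpoints
  expect_equal(as.character(code_alcohol(rep("male", 4), c(3, 4, 21, 22),
                                         1, FALSE)),
               c("light_non", "moderate", "moderate", "heavy"))
  expect_equal(as.character(code_alcohol(rep("female", 4), c(2, 3, 14, 15),
                                         1, FALSE)),
               c("light_non", "moderate", "moderate", "heavy"))
  # five drinks on one day is heavy at any weekly total
  expect_equal(as.character(code_alcohol("male", 5, 5, FALSE)), "heavy")
  expect_error(code_alcohol("male", -1, 0, FALSE), "non-negative")
})

test_that("weekly bingeing never moves a respondent out of heavy", {
  grid <- expand.grid(sex = c("male", "female"), drinks = c(0, 5, 16, 30),
                      mx = c(0, 2, 4), stringsAsFactors = FALSE)
  base <- code_alcohol(grid$sex, grid$drinks, grid$mx, FALSE)
  binged <- code_alcohol(grid$sex, grid$drinks, grid$mx, TRUE)
  expect_true(all(binged == "heavy" | base == binged))
  expect_true(all(binged[base == "heavy"] == "heavy"))
})

test_that("METs/day averages leisure activity over a 30-day month", {
  expect_equal(mets_per_day(NULL), 0)
  expect_equal(mets_per_day(data.frame(met_value = numeric(),
                                       times_per_month = numeric(),
                                       minutes_per_session = numeric())), 0)
  one <- data.frame(met_value = 3, times_per_month = 30,
                    minutes_per_session = 60)
  expect_equal(mets_per_day(one), 3)
  two <- rbind(one, data.frame(met_value = 6, times_per_month = 10,
                               minutes_per_session = 30))
  expect_equal(mets_per_day(two), mets_per_day(one) +
                 mets_per_day(two[2, , drop = FALSE]))
})

test_that("diet score reproduces worked profiles and stays in [0, 10]", {
  expect_equal(diet_score("male", 8, 1, 2, 3), 10)
  expect_equal(diet_score("female", 0, 6, 6, 0), 0)  # raw -12, recoded
  expect_equal(diet_score("male", 3, 0, 0, 2), 5)
  # sex-specific potato threshold
  expect_equal(diet_score("male", 4, 0, 6, 1), 6)
  expect_equal(diet_score("female", 4, 0, 6, 1), 4)

  grid <- expand.grid(fv = seq(0, 12, 0.5), juice = seq(0, 8, 0.5))
  s <- diet_score("male", grid$fv, grid$juice, 0, 1)
  expect_true(all(s >= 0 & s <= 10))
})

test_that("diet score is monotone in fruit/vegetable and juice frequency", {
  fv <- seq(0, 12, 0.25)
  s <- diet_score("female", fv, 0, 0, 1)
  expect_true(all(diff(s) >= 0))
  expect_equal(s[fv >= 8], rep(10, sum(fv >= 8)))  # capped at 8 points

  juice <- seq(1, 9, 0.25)
  s <- diet_score("male", 8, juice, 0, 1)
  expect_true(all(diff(s) <= 0))
  expect_equal(min(s), max(0, 2 + 8 - 10))  # penalty floored at -10
})

test_that("deprivation cells split 4 low / 4 high / 17 moderate", {
  grid <- expand.grid(m = 1:5, s = 1:5)
  cls <- deprivation_category(grid$m, grid$s)
  expect_equal(as.vector(table(cls)), c(4, 17, 4))
  expect_equal(as.character(deprivation_category(1, 2)), "low")
  expect_equal(as.character(deprivation_category(5, 4)), "high")
  expect_equal(as.character(deprivation_category(1, 5)), "moderate")
  expect_error(deprivation_category(0, 3), "1..5")
})

test_that("complete-case coding excludes and logs incomplete records", {
  ok <- make_respondent(id = 1)
  no_diet <- make_respondent(id = 2, fruit_veg_freq_per_day = NA)
  bad_age <- make_respondent(id = 3, age = 150)
  batch <- rbind(ok, no_diet, bad_age,
                 make_respondent(id = 4, smoking_status = "current",
                                 cigs_per_day = 30))
  coded <- code_exposures(batch)
  expect_equal(nrow(coded), 2)
  excl <- attr(coded, "exclusions")
  expect_equal(excl$id, c(2, 3))
  expect_equal(excl$reason, c("missing:diet", "invalid:age"))
  expect_equal(as.character(coded$smoking_class), c("non", "heavy"))
})

test_that("coding a generated cohort is deterministic and complete", {
  cfg <- cohort_config(n = 500, seed = 11)
  a <- code_exposures(generate_cohort(cfg))
  b <- code_exposures(generate_cohort(cfg))
  expect_identical(a, b)
  expect_equal(nrow(attr(a, "exclusions")), 0)
})
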