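# Wave exclusion, the auxiliary tests (exposure gap, race x zone chi-square,
# representativeness), and stratified analyses.

test_that("low-response waves are excluded exactly as configured", {
  rates <- c(A = 0.91, B = 0.65, C = 0.30, D = 0.90, E = 0.81)
  df <- data.frame(wave = rep(names(rates), each = 4), y = 1)
  out <- exclude_low_response_waves(df, rates, min_rate = 0.5)
  expect_identical(sort(unique(out$wave)), c("A", "B", "D", "E"))
  expect_identical(attr(out, "excluded_waves")$wave, "C")
  expect_equal(attr(out, "excluded_waves")$response_rate, 0.30)

  # min 0 is the identity; min 1 on rates all < 1 empties the data
  expect_identical(nrow(exclude_low_response_waves(df, rates, 0)), nrow(df))
  expect_error(exclude_low_response_waves(df, rates, 1.0), "all waves")
  expect_error(exclude_low_response_waves(df, rates[-3]), "C")
})

test_that("race x exposure chi-square matches the hand-computed Pearson form", {
  # uniform table -> statistic 0
  dfu <- expand.grid(race_ethnicity = c("a", "b"),
                     high_exposure = c(TRUE, FALSE))
  dfu <- dfu[rep(seq_len(4), 10), ]
  expect_equal(race_zone_chisquare(dfu)$statistic, 0)

  # 2x2 table [[10,20],[20,10]]: expected cells all 15,
  # sum (O-E)^2 / E = 4 * 25/15 = 20/3
  df <- rbind(
    data.frame(race_ethnicity = "a", high_exposure = rep(c(FALSE, TRUE),
                                                         c(10, 20))),
    data.frame(race_ethnicity = "b", high_exposure = rep(c(FALSE, TRUE),
                                                         c(20, 10))))
  out <- race_zone_chisquare(df)
  expect_equal(out$statistic, 20 / 3, tolerance = 1e-10)
  expect_identical(out$df, 1L)

  # five race groups give 4 degrees of freedom
  set.seed(22)
  df5 <- data.frame(
    race_ethnicity = sample(c("a", "b", "c", "d", "e"), 400, replace = TRUE),
    high_exposure = sample(c(TRUE, FALSE), 400, replace = TRUE))
  expect_identical(race_zone_chisquare(df5)$df, 4L)
  expect_error(race_zone_chisquare(
    data.frame(race_ethnicity = "a", high_exposure = TRUE)), "margin")
})

test_that("exposure gap t-test matches the closed-form Welch statistic", {
  # identical groups: difference 0, t = 0
  base <- data.frame(daily_consumer = rep(c(TRUE, FALSE, TRUE), 2),
                     high_exposure = rep(c(TRUE, FALSE), each = 3))
  out0 <- exposure_gap_ttest(base)
  expect_equal(out0$diff_pp, 0)
  expect_equal(out0$t, 0)

  set.seed(23)
  df <- data.frame(daily_consumer = rbinom(200, 1, 0.5) == 1,
                   high_exposure = rep(c(TRUE, FALSE), each = 100))
  out <- exposure_gap_ttest(df)
  x <- as.numeric(df$daily_consumer[df$high_exposure])
  y <- as.numeric(df$daily_consumer[!df$high_exposure])
  welch <- (mean(x) - mean(y)) / sqrt(var(x) / 100 + var(y) / 100)
  expect_equal(out$t, welch)
  expect_equal(out$diff_pp, 100 * (mean(x) - mean(y)))
  expect_error(exposure_gap_ttest(
    data.frame(daily_consumer = TRUE, high_exposure = TRUE)), "empty")
})

test_that("representativeness paired t-tests behave at the extremes", {
  shares <- data.frame(school_id = sprintf("s%02d", 1:19),
                       groupA = runif(19, 0.1, 0.3))
  same <- representativeness_test(shares, shares)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  inflated <- shares
  inflated$groupA <- inflated$groupA + 0.05
  out <- representativeness_test(inflated, shares)
  expect_true(out$t > 0)
  expect_lt(out$p, 0.05)

  set.seed(24)
  noisy <- shares
  noisy$groupA <- noisy$groupA + rnorm(19, 0, 0.02)
  out2 <- representativeness_test(noisy, shares)
  expect_equal(out2$mean_diff, mean(noisy$groupA - shares$groupA))
  expect_error(representativeness_test(shares[1, ], shares[1, ]), "two school")
})

test_that("paired t matches its closed form", {
  set.seed(25)
  a <- data.frame(school_id = sprintf("s%d", 1:8), g = runif(8, 0.2, 0.4))
  b <- data.frame(school_id = sprintf("s%d", 1:8), g = runif(8, 0.2, 0.4))
  out <- representativeness_test(a, b)
  d <- a$g - b$g
  expect_equal(out$t, mean(d) / (sd(d) / sqrt(8)))
  expect_equal(out$df, 7)
})

test_that("stratified analyses drop race adjustment within race strata", {
  coh <- shared_small_cohort()
  scored <- score_cohort(coh$coh$survey, default_catalog())
  scored <- exclude_low_response_waves(scored, coh$coh$response_rates)
  scored <- join_exposure(scored, coh$coh$exposure, coh$coh$membership)
  spec <- model_spec("total_kcal", "linear")
  tabs <- stratified_analysis(scored, spec, by = "race")
  g <- names(tabs)[1]
  direct <- fit_calorie_model(
    scored[scored$race_ethnicity == g, ],
    model_spec("total_kcal", "linear", covariates = character(0)))
  expect_equal(tabs[[g]]$estimate, direct$estimate, tolerance = 1e-8)
  expect_identical(attr(tabs[[g]], "spec")$covariates, character(0))
})

test_that("identical strata give identical tables", {
  coh <- shared_small_cohort()
  scored <- score_cohort(coh$coh$survey, default_catalog())
  scored <- exclude_low_response_waves(scored, coh$coh$response_rates)
  half <- scored
  half$race_ethnicity <- "g1"
  dup <- half
  dup$race_ethnicity <- "g2"
  both <- rbind(half, dup)
  tabs <- stratified_analysis(both, model_spec("total_kcal", "linear"),
                              by = "race")
  expect_equal(tabs$g1$estimate, tabs$g2$estimate)
  expect_equal(tabs$g1$p_raw, tabs$g2$p_raw)
})

test_that("empty strata are reported and skipped", {
  coh <- shared_small_cohort()
  scored <- score_cohort(coh$coh$survey, default_catalog())
  scored <- exclude_low_response_waves(scored, coh$coh$response_rates)
  scored$high_exposure <- TRUE  # no low stratum at all
  tabs <- stratified_analysis(scored, model_spec("total_kcal", "linear"),
                              by = "exposure")
  expect_false("low" %in% names(tabs))
  expect_true(any(grepl("low", attr(tabs, "skipped"))))
})

test_that("missing race is dropped from adjusted models and logged", {
  coh <- shared_small_cohort()
  scored <- score_cohort(coh$coh$survey, default_catalog())
  scored <- exclude_low_response_waves(scored, coh$coh$response_rates)
  scored$race_ethnicity[1:10] <- NA
  tab <- fit_calorie_model(scored, model_spec("total_kcal", "linear"))
  expect_identical(attr(tab, "n_dropped_missing_covariates"), 10L)
  expect_identical(sum(tab$n), nrow(scored) - 10L)
})
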