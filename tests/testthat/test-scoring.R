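# Calorie scoring: frequency mapping, per-record scoring, cohort scoring,
# and the scoring invariants (zero preservation, monotonicity, linearity,
# oracle equivalence).

test_that("frequency mapping follows the configured category values", {
  cat <- test_catalog()
  expect_identical(map_frequency("Never", cat), 0)
  # midpoint rule for the bounded category, lower bound for the open one
  expect_identical(map_frequency("2-4 times per day", cat), 3)
  expect_identical(map_frequency("5 or more times per day", cat), 5)
  expect_identical(map_frequency(NA_character_, cat), NA_real_)
  expect_error(map_frequency("sometimes", cat), "sometimes")
})

test_that("catalog constructor enforces its invariants", {
  cat <- test_catalog()
  expect_s3_class(cat, "beverage_catalog")
  bad_freq <- cat$frequency_map
  bad_freq[["Never"]] <- 1
  expect_error(beverage_catalog(cat$drink_types, cat$container_ounces,
                                cat$kcal_per_ounce, bad_freq), "Never")
  non_mono <- cat$frequency_map
  non_mono[["2-4 times per day"]] <- 0.1
  expect_error(beverage_catalog(cat$drink_types, cat$container_ounces,
                                cat$kcal_per_ounce, non_mono),
               "non-decreasing")
  bad_oz <- cat$container_ounces
  bad_oz$regular_soda[["can"]] <- -1
  expect_error(beverage_catalog(cat$drink_types, bad_oz, cat$kcal_per_ounce,
                                cat$frequency_map), "ounces")
})

test_that("all-Never records score zero and are not daily consumers", {
  cat <- test_catalog()
  sc <- score_record(all_never_record(cat), cat)
  expect_identical(sc$total_kcal, 0)
  expect_false(sc$daily_consumer)
  expect_true(all(sc$per_drink_kcal == 0))
})

test_that("sub-daily consumption contributes calories but never daily status", {
  cat <- test_catalog()
  resp <- lapply(stats::setNames(cat$drink_types, cat$drink_types),
                 function(d) c("I drink it but not every day",
                               names(cat$container_ounces[[d]])[1]))
  sc <- score_record(do.call(make_record, resp), cat)
  expect_false(sc$daily_consumer)
  expect_true(sc$total_kcal > 0)
})

test_that("per-drink calories are frequency x ounces x kcal/oz", {
  cat <- test_catalog()
  rec <- make_record(regular_soda = c("2-4 times per day", "can"))
  sc <- score_record(rec, cat)
  expect_equal(sc$per_drink_kcal[["regular_soda"]], 3 * 12 * 12.5)  # 450
  expect_equal(sc$total_kcal, 450)
  expect_true(sc$daily_consumer)
  expect_true(sc$daily_by_drink[["regular_soda"]])
})

test_that("missing responses default to zero coding; strict mode rejects", {
  cat <- test_catalog()
  rec <- make_record(regular_soda = c("2-4 times per day", NA))
  sc <- score_record(rec, cat)
  expect_identical(sc$total_kcal, 0)
  expect_false(sc$daily_consumer)
  expect_error(score_record(rec, cat, strict_missing = TRUE), "container")
  unk <- make_record(regular_soda = c("1 time per day", "barrel"))
  expect_error(score_record(unk, cat), "barrel")
})

test_that("cohort scoring matches per-record scoring row by row", {
  cat <- test_catalog()
  df <- random_survey(100, cat, seed = 42, p_missing = 0.1)
  scored <- score_cohort(df, cat)
  expect_identical(nrow(scored), 100L)
  oracle <- lapply(seq_len(100), function(i) oracle_score_row(df[i, ], cat))
  expect_equal(scored$total_kcal, vapply(oracle, `[[`, 0, "total"))
  expect_equal(scored$daily_consumer, vapply(oracle, `[[`, TRUE, "daily"))
  for (d in cat$drink_types) {
    expect_equal(scored[[paste0("kcal_", d)]],
                 vapply(oracle, function(o) o$per_drink[[d]], 0),
                 info = d)
  }
  # column total equals the sum of individual totals
  expect_equal(sum(scored$total_kcal),
               sum(vapply(oracle, `[[`, 0, "total")))
})

test_that("scoring is monotone in any one drink's frequency", {
  cat <- test_catalog()
  levels <- frequency_levels()
  base <- random_survey(25, cat, seed = 7)
  scored0 <- score_cohort(base, cat)
  for (d in cat$drink_types) {
    fcol <- paste0("freq_", d)
    idx <- match(base[[fcol]], levels)
    bump <- base
    bump[[fcol]] <- levels[pmin(idx + 1, length(levels))]
    scored1 <- score_cohort(bump, cat)
    expect_true(all(scored1$total_kcal >= scored0$total_kcal), info = d)
  }
})

test_that("total calories are the sum of independent per-drink scores", {
  cat <- test_catalog()
  df <- random_survey(40, cat, seed = 9)
  scored <- score_cohort(df, cat)
  per_drink <- rowSums(scored[paste0("kcal_", cat$drink_types)])
  expect_equal(scored$total_kcal, per_drink)
  expect_equal(scored$daily_consumer,
               rowSums(scored[paste0("daily_", cat$drink_types)]) > 0)
})

test_that("single-record cohort equals score_record output", {
  cat <- test_catalog()
  df <- random_survey(1, cat, seed = 3)
  scored <- score_cohort(df, cat)
  rec <- make_record()
  rec$responses <- lapply(stats::setNames(cat$drink_types, cat$drink_types),
                          function(d) list(frequency = df[[paste0("freq_", d)]],
                                           container = df[[paste0("container_", d)]]))
  sc <- score_record(rec, cat)
  expect_equal(scored$total_kcal, sc$total_kcal)
  expect_equal(scored$daily_consumer, sc$daily_consumer)
})

test_that("survey reader requires the key columns", {
  f <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(wave = "w1", school_id = "s1"), f,
                   row.names = FALSE)
  expect_error(read_survey(f), "race_ethnicity")
})

test_that("shipped default catalog loads and validates", {
  cat <- default_catalog()
  expect_s3_class(cat, "beverage_catalog")
  expect_length(cat$drink_types, 5)
  expect_identical(unname(cat$frequency_map[["Never"]]), 0)
})
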