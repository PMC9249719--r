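# Zone assignment, inventories, merging, the in-sample-mean exposure
# classifier, and the balance diagnostics.

test_that("points are assigned to the containing zone", {
  zones <- grid_zones(4, ncol_grid = 2)
  est <- data.frame(id = c("a", "b", "c"), category_code = "722513",
                    x = c(0.5, 1.5, 9), y = c(0.5, 1.5, 9),
                    stringsAsFactors = FALSE)
  est <- categorize_establishments(est)
  out <- assign_establishments(est, zones)
  expect_identical(out$zone_id[1], "Z01")  # centroid of the first unit square
  expect_identical(out$zone_id[2], "Z04")
  expect_true(is.na(out$zone_id[3]))       # outside every polygon
  expect_identical(attr(out, "unassigned"), 3L)
})

test_that("random points match a brute-force rectangle containment oracle", {
  zones <- grid_zones(4, ncol_grid = 2)
  set.seed(31)
  pts <- data.frame(id = sprintf("p%02d", 1:20), category_code = "445120",
                    x = runif(20, -0.5, 2.5), y = runif(20, -0.5, 2.5),
                    stringsAsFactors = FALSE)
  out <- assign_establishments(categorize_establishments(pts), zones)
  oracle <- vapply(seq_len(20), function(i) {
    hit <- NA_character_
    for (zid in zones$zone_id) {
      ring <- zones$polygons[[zid]]
      if (pts$x[i] > min(ring[, 1]) && pts$x[i] < max(ring[, 1]) &&
          pts$y[i] > min(ring[, 2]) && pts$y[i] < max(ring[, 2])) {
        hit <- zid
        break
      }
    }
    hit
  }, "")
  expect_identical(out$zone_id, oracle)
})

test_that("overlapping zones trigger an error naming the zones", {
  zones <- grid_zones(2)
  zones$polygons$Z02 <- zones$polygons$Z01  # duplicate geometry
  est <- data.frame(id = "a", category_code = "722513", x = 0.5, y = 0.5,
                    stringsAsFactors = FALSE)
  expect_error(assign_establishments(categorize_establishments(est), zones),
               "Z01.*Z02")
})

test_that("inventories count establishments by category per zone", {
  zones <- grid_zones(3)
  empty <- data.frame(zone_id = character(0), category = character(0))
  inv0 <- build_inventories(empty, zones)
  expect_identical(nrow(inv0), 3L)
  expect_true(all(inv0$unhealthy_count == 0))

  est <- data.frame(zone_id = c(rep("Z01", 4)),
                    category = c(rep("fast_food", 3), "convenience"),
                    stringsAsFactors = FALSE)
  inv <- build_inventories(est, zones)
  expect_identical(inv$unhealthy_count[inv$zone_id == "Z01"], 4)
  expect_identical(inv$unhealthy_count[inv$zone_id == "Z02"], 0)
  expect_error(build_inventories(
    data.frame(zone_id = "Z01", category = "bakery"), zones), "bakery")
})

test_that("inventory counts match an independent group-by tally", {
  zones <- grid_zones(4)
  set.seed(8)
  est <- data.frame(
    zone_id = sample(zones$zone_id, 30, replace = TRUE),
    category = sample(c("supermarket_grocery", "fast_food", "convenience",
                        "gas_station_food"), 30, replace = TRUE),
    stringsAsFactors = FALSE)
  inv <- build_inventories(est, zones)
  tally <- table(factor(est$zone_id, zones$zone_id), est$category)
  for (cat in colnames(tally)) {
    expect_equal(inv[[cat]], as.integer(tally[, cat]), info = cat)
  }
  expect_equal(inv$unhealthy_count,
               inv$fast_food + inv$convenience + inv$gas_station_food)
})

test_that("industry code table drives categorization and rejects unknowns", {
  est <- data.frame(category_code = c("445110", "722513", "445120", "447110"))
  out <- categorize_establishments(est)
  expect_identical(out$category, c("supermarket_grocery", "fast_food",
                                   "convenience", "gas_station_food"))
  expect_error(categorize_establishments(data.frame(category_code = "99")),
               "99")
  custom <- data.frame(code = "1", category = "fast_food")
  out2 <- categorize_establishments(data.frame(category_code = "1"), custom)
  expect_identical(out2$category, "fast_food")
})

test_that("zone merging is additive and identity on a single zone", {
  inv <- inventory_from_counts(c(5, 7, 3), grocery = c(1, 2, 0),
                               enrollment = c(100, 150, 120))
  one <- merge_zones(inv, "Z01", new_id = "Z01")
  expect_equal(sort(one$unhealthy_count), sort(inv$unhealthy_count))
  merged <- merge_zones(inv, c("Z01", "Z02"), new_id = "M")
  m <- merged[merged$zone_id == "M", ]
  expect_equal(m$unhealthy_count, 12)
  expect_equal(m$supermarket_grocery, 3)
  expect_equal(m$enrollment, 250)
  expect_identical(nrow(merged), 2L)
  expect_error(merge_zones(inv, "Z99"), "Z99")
})

test_that("classification uses a strict in-sample-mean threshold", {
  # identical counts: mean equals every count, strict comparison -> all low
  same <- classify_zones(inventory_from_counts(c(4, 4, 4)))
  expect_false(any(same$high_exposure))
  tri <- classify_zones(inventory_from_counts(c(10, 20, 30)))
  expect_identical(attr(tri, "threshold"), 20)
  expect_identical(tri$high_exposure, c(FALSE, FALSE, TRUE))
  single <- classify_zones(inventory_from_counts(5))
  expect_false(single$high_exposure)
  empty <- inventory_from_counts(c(1, 2))[0, ]
  expect_error(classify_zones(empty), "at least one")
})

test_that("classification is scale- and permutation-invariant", {
  set.seed(21)
  for (i in 1:20) {
    counts <- rpois(12, 9) + 1
    base <- classify_zones(inventory_from_counts(counts))
    scaled <- classify_zones(inventory_from_counts(counts * sample(1:7, 1)))
    expect_identical(scaled$high_exposure, base$high_exposure)
    perm <- sample(length(counts))
    shuffled <- classify_zones(inventory_from_counts(counts[perm]))
    expect_identical(shuffled$high_exposure, base$high_exposure[perm])
    if (length(unique(counts)) > 1) {
      expect_true(any(base$high_exposure))
      expect_true(any(!base$high_exposure))
    }
  }
})

test_that("merging zones that were each high keeps the coding unchanged", {
  # 16 low zones plus three zones each individually above the mean
  counts <- c(rep(8, 16), 20, 20, 20)
  inv <- inventory_from_counts(counts)
  pre <- classify_zones(inv)
  high_ids <- pre$zone_id[pre$high_exposure]
  expect_length(high_ids, 3)

  merged <- merge_zones(inv, high_ids, new_id = "combined")
  post <- classify_zones(merged)
  expect_true(post$high_exposure[post$zone_id == "combined"])
  # and every untouched zone keeps its low coding
  expect_false(any(post$high_exposure[post$zone_id != "combined"]))
})

test_that("balance diagnostics match the closed-form Welch statistic", {
  inv <- inventory_from_counts(c(12, 14, 16, 5, 6, 7),
                               grocery = c(4, 5, 6, 3, 4, 5),
                               enrollment = c(210, 220, 230, 200, 210, 215))
  emap <- classify_zones(inv)
  out <- zone_balance_tests(inv, emap)
  g_hi <- inv$supermarket_grocery[emap$high_exposure]
  g_lo <- inv$supermarket_grocery[!emap$high_exposure]
  welch <- (mean(g_hi) - mean(g_lo)) /
    sqrt(var(g_hi) / length(g_hi) + var(g_lo) / length(g_lo))
  expect_equal(out$tests$t[out$tests$measure == "grocery"], welch)
  expect_identical(out$descriptives$n_zones, c(3L, 3L))
  expect_equal(out$descriptives$fast_food_mean, c(14, 6))

  # identical groups -> t = 0, p = 1
  inv2 <- inventory_from_counts(c(12, 14, 16, 5, 6, 7),
                                grocery = c(1, 2, 3, 1, 2, 3))
  out2 <- zone_balance_tests(inv2, classify_zones(inv2))
  expect_equal(out2$tests$t[out2$tests$measure == "grocery"], 0)
  expect_equal(out2$tests$p[out2$tests$measure == "grocery"], 1)

  # one empty exposure group -> diagnostics undefined, with explanation
  inv3 <- inventory_from_counts(c(4, 4, 4))
  out3 <- zone_balance_tests(inv3, classify_zones(inv3))
  expect_true(is.na(out3$tests))
  expect_match(attr(out3, "explanation"), "empty")
})
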