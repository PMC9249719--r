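# Fixture builders shared across the test files. All fixtures are built in
# code; tests pin explicit catalogs so no shipped placeholder value is ever
# treated as ground truth.

test_catalog <- function() {
  beverage_catalog(
    drink_types = c("regular_soda", "fruit_drink", "sports_drink",
                    "energy_drink", "flavored_water_tea"),
    container_ounces = list(
      regular_soda = c(glass = 8, can = 12, bottle = 20),
      fruit_drink = c(glass = 8, pouch = 6, juice_box = 6.75, bottle = 20),
      sports_drink = c(glass = 8, bottle = 20),
      energy_drink = c(can = 12),
      flavored_water_tea = c(glass = 8, bottle = 20)),
    kcal_per_ounce = list(
      regular_soda = c(glass = 12.5, can = 12.5, bottle = 12.5),
      fruit_drink = c(glass = 14, pouch = 14, juice_box = 14, bottle = 14),
      sports_drink = c(glass = 6.5, bottle = 6.5),
      energy_drink = c(can = 13),
      flavored_water_tea = c(glass = 8, bottle = 8)),
    frequency_map = c("Never" = 0, "I drink it but not every day" = 0.5,
                      "1 time per day" = 1, "2-4 times per day" = 3,
                      "5 or more times per day" = 5))
}

# a survey-record list for score_record()
make_record <- function(...) {
  resp <- list(...)
  list(student_id = "t1", wave = "w1", school_id = "s1",
       race_ethnicity = "white",
       responses = lapply(resp, function(x) {
         list(frequency = x[[1]], container = if (length(x) > 1) x[[2]] else NA)
       }))
}

all_never_record <- function(catalog = test_catalog()) {
  resp <- stats::setNames(
    rep(list(c("Never")), length(catalog$drink_types)), catalog$drink_types)
  do.call(make_record, resp)
}

# random survey data frame over the fixture catalog's categories
random_survey <- function(n, catalog = test_catalog(), seed = 1,
                          p_missing = 0) {
  set.seed(seed)
  df <- data.frame(
    student_id = sprintf("r%04d", seq_len(n)),
    wave = sample(c("w1", "w2"), n, replace = TRUE),
    school_id = sample(c("s1", "s2", "s3"), n, replace = TRUE),
    race_ethnicity = sample(c("Asian", "Black", "Hispanic", "multiple_other",
                              "white"), n, replace = TRUE),
    stringsAsFactors = FALSE)
  for (d in catalog$drink_types) {
    freq <- sample(frequency_levels(), n, replace = TRUE)
    cont <- vapply(seq_len(n), function(i) {
      sample(names(catalog$container_ounces[[d]]), 1)
    }, "")
    if (p_missing > 0) {
      freq[stats::runif(n) < p_missing] <- NA
      cont[stats::runif(n) < p_missing] <- NA
    }
    df[[paste0("freq_", d)]] <- freq
    df[[paste0("container_", d)]] <- cont
  }
  df
}

# independent brute-force scoring oracle: triple lookup and multiply, written
# against the raw catalog lists with no shared code path
oracle_score_row <- function(row, catalog) {
  total <- 0
  daily <- FALSE
  per_drink <- numeric(0)
  for (d in catalog$drink_types) {
    f <- row[[paste0("freq_", d)]]
    co <- row[[paste0("container_", d)]]
    kcal <- 0
    if (!is.na(f) && f != "Never" && !is.na(co)) {
      times <- unname(catalog$frequency_map[[f]])
      oz <- catalog$container_ounces[[d]][[co]]
      kpo <- catalog$kcal_per_ounce[[d]][[co]]
      kcal <- times * oz * kpo
    }
    if (!is.na(f) && !is.na(co) &&
        f %in% c("1 time per day", "2-4 times per day",
                 "5 or more times per day")) {
      daily <- TRUE
    }
    per_drink[d] <- kcal
    total <- total + kcal
  }
  list(total = total, daily = daily, per_drink = per_drink)
}

# a unit-square grid of k zones, one school per zone
grid_zones <- function(k, ncol_grid = ceiling(sqrt(k))) {
  zone_id <- sprintf("Z%02d", seq_len(k))
  polys <- lapply(seq_len(k) - 1L, function(i) {
    x0 <- i %% ncol_grid; y0 <- i %/% ncol_grid
    cbind(c(x0, x0 + 1, x0 + 1, x0), c(y0, y0, y0 + 1, y0 + 1))
  })
  names(polys) <- zone_id
  structure(list(
    zone_id = zone_id, polygons = polys,
    school_ids = stats::setNames(as.list(sprintf("S%02d", seq_len(k))),
                                 zone_id),
    enrollment = stats::setNames(rep(200, k), zone_id)),
    class = "zone_set")
}

# an inventory data frame built directly from per-zone unhealthy counts
inventory_from_counts <- function(unhealthy, grocery = NULL,
                                  enrollment = NULL) {
  k <- length(unhealthy)
  inv <- data.frame(zone_id = sprintf("Z%02d", seq_len(k)),
                    supermarket_grocery = if (is.null(grocery)) rep(0L, k)
                                          else grocery,
                    fast_food = as.integer(unhealthy),
                    convenience = 0L, gas_station_food = 0L,
                    stringsAsFactors = FALSE)
  inv$unhealthy_count <- inv$fast_food + inv$convenience +
    inv$gas_station_food
  if (!is.null(enrollment)) inv$enrollment <- enrollment
  class(inv) <- c("zone_inventory", class(inv))
  inv
}

# scaled-down study config for pipeline-level tests
scaled_config <- function(n_per_wave = 150, n_schools = 6, n_high = 2,
                          sampling = "balanced") {
  cfg <- default_study_config()
  cfg$waves$sample_size <- rep(as.integer(n_per_wave), nrow(cfg$waves))
  cfg$n_schools <- as.integer(n_schools)
  cfg$n_high_regime <- as.integer(n_high)
  cfg$sampling <- sampling
  cfg
}

# small generated cohort reused by several test files (built once per run)
shared_small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- scaled_config(n_per_wave = 500, n_schools = 6, n_high = 2)
      city <- generate_city(cfg, seed = 11)
      coh <- generate_cohort(cfg, city, seed = 12)
      cache <<- list(cfg = cfg, city = city, coh = coh)
    }
    cache
  }
})

# one full pipeline run on the shared cohort, built lazily and reused
shared_pipeline_result <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      coh <- shared_small_cohort()
      cache <<- run_pipeline(coh$coh$survey, coh$city$establishments,
                             coh$city$zones, catalog = default_catalog(),
                             response_rates = coh$coh$response_rates,
                             seed = 1)
    }
    cache
  }
})
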