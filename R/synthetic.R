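#' Cohort generator configuration
#'
#' Bundles every quantity the synthetic generator needs: survey waves with
#' sample sizes and response rates, school/zone structure, race mix,
#' race-specific probabilities of living in a high unhealthy-retail exposure
#' zone, per-wave prevalence and calorie calibration targets, establishment
#' count distributions, and between-school heterogeneity scales. See
#' [default_study_config()] for the shipped calibration.
#'
#' @param waves data frame with `wave`, `response_rate`, `sample_size`.
#' @param n_schools number of schools (one attendance zone each).
#' @param n_high_regime number of zones drawing establishment counts from the
#'   high-density regime.
#' @param race_mix named probabilities over the five race/ethnicity groups
#'   (must sum to 1).
#' @param high_exposure_prob named per-race probability of attending a school
#'   in a high-exposure zone.
#' @param overall_high_share the overall share of students in high-exposure
#'   zones implied by the calibration (reference value; generation uses
#'   `high_exposure_prob`).
#' @param prevalence list with `overall_by_wave` (named, proportions),
#'   `race_final` (named, final-wave proportions by race) and `gap_by_wave`
#'   (named, high minus low exposure difference per wave, proportion scale).
#' @param kcal list with `overall_by_wave`, `race_base`, `race_final` (kcal/
#'   day) and `exposure_gap_by_wave` (kcal).
#' @param establishment_means data frame: `category`, `high`, `low` Poisson
#'   means per zone.
#' @param school_effect_sd_logit between-school SD of the prevalence random
#'   intercept, logit scale.
#' @param school_effect_sd_kcal between-school SD of the calorie shift,
#'   kcal/day.
#' @param drink_weights named relative popularity of the five drink types
#'   (sums to 1).
#' @param container_probs named list: per drink, named probabilities over its
#'   catalog containers.
#' @param sampling `"balanced"` (default) assigns daily-consumer counts per
#'   school cell by randomized rounding of the target probability, so realized
#'   stratum rates match the calibration up to rounding -- the standard way
#'   calibrated synthetic populations are constructed; `"bernoulli"` draws
#'   each student independently.
#' @param seed default RNG seed.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(waves, n_schools, n_high_regime, race_mix,
                          high_exposure_prob, overall_high_share,
                          prevalence, kcal, establishment_means,
                          school_effect_sd_logit = 0.3,
                          school_effect_sd_kcal = 30,
                          drink_weights, container_probs,
                          sampling = c("balanced", "bernoulli"),
                          seed = 1L) {
  cfg <- list(waves = waves, n_schools = n_schools,
              n_high_regime = n_high_regime, race_mix = race_mix,
              high_exposure_prob = high_exposure_prob,
              overall_high_share = overall_high_share,
              prevalence = prevalence, kcal = kcal,
              establishment_means = establishment_means,
              school_effect_sd_logit = school_effect_sd_logit,
              school_effect_sd_kcal = school_effect_sd_kcal,
              drink_weights = drink_weights,
              container_probs = container_probs,
              sampling = match.arg(sampling), seed = as.integer(seed))
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  w <- cfg$waves
  stopifnot(is.data.frame(w),
            all(c("wave", "response_rate", "sample_size") %in% names(w)),
            all(w$sample_size > 0), all(w$response_rate >= 0),
            all(w$response_rate <= 1))
  if (abs(sum(cfg$race_mix) - 1) > 1e-8) stop("race_mix must sum to 1")
  if (any(cfg$race_mix < 0) || any(cfg$race_mix > 1)) {
    stop("race_mix entries must be probabilities")
  }
  races <- names(cfg$race_mix)
  if (!setequal(names(cfg$high_exposure_prob), races)) {
    stop("high_exposure_prob must be named by the race groups")
  }
  if (any(cfg$high_exposure_prob < 0 | cfg$high_exposure_prob > 1)) {
    stop("high_exposure_prob entries must be probabilities")
  }
  wl <- as.character(w$wave)
  for (nm in c("overall_by_wave", "gap_by_wave")) {
    if (!setequal(names(cfg$prevalence[[nm]]), wl)) {
      stop("prevalence$", nm, " must be named by the waves")
    }
  }
  if (!setequal(names(cfg$prevalence$race_final), races)) {
    stop("prevalence$race_final must be named by the race groups")
  }
  if (any(unlist(cfg$prevalence[c("overall_by_wave", "race_final")]) <= 0) ||
      any(unlist(cfg$prevalence[c("overall_by_wave", "race_final")]) >= 1)) {
    stop("prevalence targets must lie strictly in (0, 1)")
  }
  for (nm in c("overall_by_wave", "exposure_gap_by_wave")) {
    if (!setequal(names(cfg$kcal[[nm]]), wl)) {
      stop("kcal$", nm, " must be named by the waves")
    }
  }
  stopifnot(cfg$n_schools >= 2, cfg$n_high_regime >= 1,
            cfg$n_high_regime < cfg$n_schools,
            cfg$school_effect_sd_logit >= 0, cfg$school_effect_sd_kcal >= 0)
  if (abs(sum(cfg$drink_weights) - 1) > 1e-8) {
    stop("drink_weights must sum to 1")
  }
  for (d in names(cfg$container_probs)) {
    if (abs(sum(cfg$container_probs[[d]]) - 1) > 1e-8) {
      stop("container_probs for '", d, "' must sum to 1")
    }
  }
  invisible(cfg)
}

#' Shipped study-condition calibration
#'
#' The default configuration encodes the published study conditions the
#' generator emulates: four analysis waves plus one low-response wave
#' (response rates 91/65/30/90/81%, about 13,100 analysed students), 19
#' schools each with its own attendance zone, a five-group race/ethnicity mix,
#' overall daily-consumption prevalence declining from 49.4% to 36.9% with
#' final-wave race-specific levels (Asian 22.5%, Black 58.5%, Hispanic 49.1%,
#' multiple/other 37.7%, white 33.0%), mean daily sugary-drink calories
#' declining from 220 to 158 kcal, a pooled high-vs-low exposure prevalence
#' gap of about 7.1 percentage points (widening over time, about 9.7 by the
#' final wave), race-specific probabilities of living in a high-exposure zone
#' (21.6/32.3/33.2/26.6/19.8%), and zone establishment means (fast food
#' 14.2 vs 7.3; convenience + gas 3.8 vs 2.4 per zone). Interior-wave levels
#' are not published and are set to a smooth decline; the between-school SDs
#' (0.3 logits, 30 kcal) are likewise unpublished defaults.
#'
#' @return A `cohort_config`.
#' @export
default_study_config <- function() {
  waves <- data.frame(
    wave = c("2012-13", "2013-14", "2014-15", "2015-16", "2016-17"),
    response_rate = c(0.91, 0.65, 0.30, 0.90, 0.81),
    # one grade cohort of ~4015 students per year; sample = enrollment x rate,
    # giving ~13,130 students across the four analysis waves
    sample_size = c(3654L, 2610L, 1205L, 3614L, 3252L),
    stringsAsFactors = FALSE)
  wl <- waves$wave
  races <- c("Asian", "Black", "Hispanic", "multiple_other", "white")
  # county shares as printed sum to 101.7%; normalized here
  mix <- c(Asian = 0.193, Black = 0.204, Hispanic = 0.073,
           multiple_other = 0.044, white = 0.503)
  mix <- mix / sum(mix)
  cohort_config(
    waves = waves,
    n_schools = 19L,
    n_high_regime = 5L,
    race_mix = mix,
    high_exposure_prob = c(Asian = 0.216, Black = 0.323, Hispanic = 0.332,
                           multiple_other = 0.266, white = 0.198),
    overall_high_share = 0.246,
    prevalence = list(
      overall_by_wave = stats::setNames(
        c(0.494, 0.462, 0.440, 0.418, 0.369), wl),
      race_final = c(Asian = 0.225, Black = 0.585, Hispanic = 0.491,
                     multiple_other = 0.377, white = 0.330),
      gap_by_wave = stats::setNames(
        c(0.055, 0.063, 0.066, 0.070, 0.097), wl)),
    kcal = list(
      overall_by_wave = stats::setNames(c(220, 196, 185, 175, 158), wl),
      race_base = c(Asian = 150, Black = 300, Hispanic = 300,
                    multiple_other = 197, white = 197),
      race_final = c(Asian = 115, Black = 235, Hispanic = 235,
                     multiple_other = 132, white = 132),
      exposure_gap_by_wave = stats::setNames(c(20, 22, 23, 25, 32), wl)),
    establishment_means = data.frame(
      category = c("fast_food", "convenience", "gas_station_food",
                   "supermarket_grocery"),
      high = c(14.2, 2.5, 1.3, 3.2),
      low = c(7.3, 1.6, 0.8, 2.6),
      stringsAsFactors = FALSE),
    drink_weights = c(regular_soda = 0.25, fruit_drink = 0.35,
                      sports_drink = 0.20, energy_drink = 0.08,
                      flavored_water_tea = 0.12),
    container_probs = list(
      regular_soda = c(glass = 0.2, can = 0.5, bottle = 0.3),
      fruit_drink = c(glass = 0.2, pouch = 0.3, juice_box = 0.25,
                      bottle = 0.25),
      sports_drink = c(glass = 0.2, bottle = 0.8),
      energy_drink = c(can = 1.0),
      flavored_water_tea = c(glass = 0.4, bottle = 0.6)),
    seed = 20120901L)
}

#' Generate a synthetic city: attendance zones, schools, establishments
#'
#' Zones tile a planar rectangle with disjoint unit squares, one school per
#' zone. A configured number of zones draw establishment counts from the
#' high-density regime and the rest from the low regime; counts per category
#' scatter with bounded relative dispersion around the regime mean, and
#' establishment points are uniform within their zone.
#'
#' @param config a `cohort_config`.
#' @param seed RNG seed (default `config$seed`).
#' @param n_zones optional override of the number of zones (schools); the
#'   high-regime count is scaled proportionally. Useful for large calibration
#'   checks.
#' @return list with `zones` (a `zone_set` with `school_ids`, `enrollment`,
#'   and a `regime` attribute giving each zone's generating regime),
#'   `establishments` (data frame `id`, `category_code`, `category`, `x`,
#'   `y`), and `schools` (data frame `school_id`, `zone_id`, `enrollment`).
#' @export
generate_city <- function(config, seed = config$seed, n_zones = NULL) {
  validate_cohort_config(config)
  set.seed(seed)
  n <- if (is.null(n_zones)) config$n_schools else as.integer(n_zones)
  n_high <- if (is.null(n_zones)) config$n_high_regime else
    max(1L, round(n * config$n_high_regime / config$n_schools))
  ncol_grid <- ceiling(sqrt(n))
  zone_id <- sprintf("Z%03d", seq_len(n))
  school_id <- sprintf("S%03d", seq_len(n))
  polys <- lapply(seq_len(n) - 1L, function(i) {
    x0 <- i %% ncol_grid
    y0 <- i %/% ncol_grid
    cbind(c(x0, x0 + 1, x0 + 1, x0), c(y0, y0, y0 + 1, y0 + 1))
  })
  names(polys) <- zone_id
  regime <- rep("low", n)
  regime[sample.int(n, n_high)] <- "high"
  # one grade cohort per school; enrollment balanced across exposure regimes
  per_school <- sum(config$waves$sample_size[1]) / config$waves$response_rate[1] /
    config$n_schools
  enrollment <- pmax(40, round(stats::rnorm(n, per_school, per_school * 0.08)))
  names(enrollment) <- zone_id

  em <- config$establishment_means
  code_table <- default_code_table()
  rows <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(nrow(em))) {
      # bounded relative dispersion (+/-15%) around the regime mean: zone
      # retail densities are stable features of a neighborhood, and the
      # high/low regimes are well separated, so classification under the
      # in-sample-mean rule reproduces the configured regime structure
      cnt <- round(em[[regime[i]]][j] * stats::runif(1, 0.85, 1.15))
      if (cnt == 0) next
      x0 <- (i - 1L) %% ncol_grid
      y0 <- (i - 1L) %/% ncol_grid
      rows[[length(rows) + 1L]] <- data.frame(
        category = em$category[j],
        x = stats::runif(cnt, x0, x0 + 1),
        y = stats::runif(cnt, y0, y0 + 1),
        stringsAsFactors = FALSE)
    }
  }
  est <- if (length(rows)) do.call(rbind, rows) else
    data.frame(category = character(0), x = numeric(0), y = numeric(0))
  if (nrow(est)) {
    est$id <- sprintf("E%05d", seq_len(nrow(est)))
    est$category_code <- code_table$code[match(est$category, code_table$category)]
    est <- est[c("id", "category_code", "category", "x", "y")]
  } else {
    est$id <- character(0); est$category_code <- character(0)
  }
  zones <- structure(
    list(zone_id = zone_id, polygons = polys,
         school_ids = stats::setNames(as.list(school_id), zone_id),
         enrollment = enrollment),
    class = "zone_set", regime = stats::setNames(regime, zone_id))
  list(zones = zones, establishments = est,
       schools = data.frame(school_id = school_id, zone_id = zone_id,
                            enrollment = unname(enrollment),
                            stringsAsFactors = FALSE))
}

# ---- prevalence calibration -------------------------------------------------

# Solve per-wave intercepts and exposure effects so that, under the configured
# race mix and race-specific zone placement, the model-implied overall
# prevalence and high-low gap match the configured wave targets. Race offsets
# are held constant across waves on the logit scale.
calibrate_prevalence_cells <- function(config) {
  races <- names(config$race_mix)
  m <- config$race_mix
  h <- config$high_exposure_prob[races]
  hbar <- sum(m * h)
  d_r <- stats::qlogis(config$prevalence$race_final[races])
  wl <- as.character(config$waves$wave)

  cell <- function(a, g, e) stats::plogis(
    matrix(d_r, ncol = 1) + a + g * (e - hbar))  # races x 1
  overall_implied <- function(a, g) {
    sum(m * (h * cell(a, g, 1) + (1 - h) * cell(a, g, 0)))
  }
  gap_implied <- function(a, g) {
    sum(m * h * cell(a, g, 1)) / hbar -
      sum(m * (1 - h) * cell(a, g, 0)) / (1 - hbar)
  }
  out <- list()
  for (w in wl) {
    p_t <- config$prevalence$overall_by_wave[[w]]
    g_t <- config$prevalence$gap_by_wave[[w]]
    solve_a <- function(g) stats::uniroot(
      function(a) overall_implied(a, g) - p_t, c(-10, 10), tol = 1e-10)$root
    g <- stats::uniroot(function(g) gap_implied(solve_a(g), g) - g_t,
                        c(0, 5), tol = 1e-9, extendInt = "upX")$root
    a <- solve_a(g)
    out[[w]] <- data.frame(
      wave = w, race = rep(races, 2), exposure = rep(c("high", "low"),
                                                     each = length(races)),
      p = c(cell(a, g, 1), cell(a, g, 0)), stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# Per (wave, race) calorie targets: race trajectories interpolated between the
# configured baseline and final levels, rescaled per wave so the mix-weighted
# overall mean hits the configured wave target exactly.
calibrate_kcal_cells <- function(config) {
  races <- names(config$race_mix)
  m <- config$race_mix
  wl <- as.character(config$waves$wave)
  ov <- config$kcal$overall_by_wave[wl]
  base <- config$kcal$race_base[races]
  fin <- config$kcal$race_final[races]
  frac <- (ov[[1]] - ov) / (ov[[1]] - ov[[length(ov)]])  # 0 at baseline, 1 final
  out <- list()
  for (i in seq_along(wl)) {
    k_r <- base + (fin - base) * frac[i]
    k_r <- k_r * ov[[i]] / sum(m * k_r)  # exact overall wave mean
    out[[wl[i]]] <- data.frame(wave = wl[i], race = races, kcal = unname(k_r),
                               stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# ---- calorie-intensity solver ----------------------------------------------

# Expected serving kcal per drink under the configured container mix.
expected_serving_kcal <- function(config, catalog) {
  vapply(names(config$drink_weights), function(d) {
    pr <- config$container_probs[[d]]
    sum(pr * vapply(names(pr), function(cont) serving_kcal(catalog, d, cont), 0))
  }, 0)
}

# Closed-form expected scored kcal/day given daily status and intensity theta.
# Sub-daily reporting of drink d happens w.p. 1 - exp(-theta * W_d); a daily
# consumer's primary drink (chosen by popularity) escalates through the daily
# frequency categories via a Binomial(2, theta/(1+theta)) mixture.
kcal_expectation <- function(theta, config, ek, freq_map) {
  W <- config$drink_weights
  f_sub <- freq_map[["I drink it but not every day"]]
  f_daily <- c(freq_map[["1 time per day"]], freq_map[["2-4 times per day"]],
               freq_map[["5 or more times per day"]])
  q <- 1 - exp(-theta * W)
  r <- theta / (1 + theta)
  Ef <- (1 - r)^2 * f_daily[1] + 2 * r * (1 - r) * f_daily[2] + r^2 * f_daily[3]
  E0 <- sum(q * f_sub * ek)
  E1 <- Ef * sum(W * ek) + f_sub * sum(q * ek * (1 - W))
  c(nondaily = E0, daily = E1)
}

solve_theta <- function(target, p_daily, config, ek, freq_map,
                        theta_max = 400) {
  f <- function(th) {
    e <- kcal_expectation(th, config, ek, freq_map)
    p_daily * e[["daily"]] + (1 - p_daily) * e[["nondaily"]] - target
  }
  if (f(0) >= 0) return(0)
  if (f(theta_max) <= 0) return(theta_max)
  stats::uniroot(f, c(0, theta_max), tol = 1e-7)$root
}

# ---- cohort generation ------------------------------------------------------

#' Generate a synthetic survey cohort
#'
#' Students are assigned a wave, race/ethnicity (by the configured mix), and a
#' school: race-specific probabilities of attending a school in a high
#' unhealthy-retail exposure zone reproduce the configured race-by-place
#' pattern. Exposure groups are the zones' realized classification under the
#' in-sample-mean rule ([classify_zones()] applied to the generated city), so
#' the cohort is internally consistent with the downstream classifier.
#' Daily-consumer status follows the calibrated (wave x race x exposure) cell
#' probabilities with a centered school-level random intercept on the logit
#' scale; given status, frequency and container categories are drawn so the
#' expected scored calories match the calibrated cell means under `catalog`
#' (the category-mixture intensity is solved numerically per cell).
#'
#' @param config a `cohort_config`.
#' @param city output of [generate_city()].
#' @param seed RNG seed (default `config$seed + 1`).
#' @param catalog the beverage catalog used to invert calorie targets into
#'   category mixtures; must be the catalog later used for scoring.
#' @return list with `survey` (one row per student: ids, demographics and the
#'   per-drink frequency/container responses), `response_rates`,
#'   `population_shares` (per-school race shares of the full grade
#'   population), `exposure` (the realized `exposure_map`), `inventories`,
#'   and `membership` (school to zone table).
#' @export
generate_cohort <- function(config, city, seed = config$seed + 1L,
                            catalog = default_catalog()) {
  validate_cohort_config(config)
  set.seed(seed)
  est <- categorize_establishments(city$establishments)
  est <- assign_establishments(est, city$zones)
  inv <- build_inventories(est, city$zones)
  emap <- classify_zones(inv)
  if (all(emap$high_exposure) || !any(emap$high_exposure)) {
    stop("degenerate city: all zones classified alike; cannot allocate ",
         "exposure groups")
  }
  membership <- zone_membership(city$zones)
  sch <- city$schools
  sch$high <- emap$high_exposure[match(sch$zone_id, emap$zone_id)]

  races <- names(config$race_mix)
  wl <- as.character(config$waves$wave)
  pcell <- calibrate_prevalence_cells(config)
  kcell <- calibrate_kcal_cells(config)
  hbar <- sum(config$race_mix * config$high_exposure_prob[races])
  ek <- expected_serving_kcal(config, catalog)
  freq_map <- catalog$frequency_map

  # centered school effects, within exposure group so group contrasts are not
  # distorted by the finite number of schools
  b_prev <- stats::rnorm(nrow(sch), 0, config$school_effect_sd_logit)
  b_kcal <- stats::rnorm(nrow(sch), 0, config$school_effect_sd_kcal)
  for (grp in unique(sch$high)) {
    idx <- sch$high == grp
    b_prev[idx] <- b_prev[idx] - mean(b_prev[idx])
    b_kcal[idx] <- b_kcal[idx] - mean(b_kcal[idx])
  }
  names(b_prev) <- names(b_kcal) <- sch$school_id

  students <- list()
  for (w in wl) {
    n_w <- config$waves$sample_size[config$waves$wave == w]
    n_race <- largest_remainder(n_w, config$race_mix)
    for (r in races) {
      n_r <- n_race[[r]]
      if (n_r == 0) next
      n_hi <- largest_remainder(n_r, c(high = config$high_exposure_prob[[r]],
                                       low = 1 - config$high_exposure_prob[[r]]))
      for (e in c("high", "low")) {
        n_e <- n_hi[[e]]
        if (n_e == 0) next
        grp_schools <- sch$school_id[sch$high == (e == "high")]
        n_s <- largest_remainder(
          n_e, stats::setNames(rep(1 / length(grp_schools),
                                   length(grp_schools)), grp_schools))
        p_target <- pcell$p[pcell$wave == w & pcell$race == r &
                              pcell$exposure == e]
        # per-school probabilities: common offset solved so the school-size
        # weighted mean equals the calibrated cell probability
        bs <- b_prev[grp_schools]
        ns <- unlist(n_s)
        x <- stats::uniroot(function(x) {
          sum(ns * stats::plogis(x + bs)) / sum(ns) - p_target
        }, c(-15, 15), tol = 1e-9)$root
        p_s <- stats::plogis(x + bs)
        k_base <- kcell$kcal[kcell$wave == w & kcell$race == r] +
          config$kcal$exposure_gap_by_wave[[w]] * ((e == "high") - hbar)
        for (s in grp_schools) {
          if (n_s[[s]] == 0) next
          n_stu <- n_s[[s]]
          daily <- draw_daily(n_stu, p_s[[s]], config$sampling)
          p_hat <- mean(daily)
          theta <- solve_theta(max(1, k_base + b_kcal[[s]]), p_hat, config,
                               ek, freq_map)
          students[[length(students) + 1L]] <- data.frame(
            wave = w, school_id = s, race_ethnicity = r,
            high_exposure = (e == "high"), daily = daily, theta = theta,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  stu <- do.call(rbind, students)
  stu <- stu[sample.int(nrow(stu)), , drop = FALSE]  # shuffle row order
  rownames(stu) <- NULL
  stu$student_id <- sprintf("P%06d", seq_len(nrow(stu)))
  stu$gender <- sample(c("female", "male"), nrow(stu), replace = TRUE)

  survey <- draw_responses(stu, config, catalog)
  survey$zone_id <- membership$zone_id[match(survey$school_id,
                                             membership$school_id)]
  cols <- c("student_id", "wave", "school_id", "zone_id", "race_ethnicity",
            "gender",
            paste0("freq_", names(config$drink_weights)),
            paste0("container_", names(config$drink_weights)))
  survey <- survey[cols]

  list(survey = survey,
       response_rates = config$waves[c("wave", "response_rate")],
       population_shares = population_shares(stu, config),
       exposure = emap, inventories = inv, membership = membership)
}

draw_daily <- function(n, p, sampling) {
  if (sampling == "bernoulli") {
    return(stats::rbinom(n, 1, p) == 1)
  }
  k <- floor(n * p) + (stats::runif(1) < (n * p - floor(n * p)))
  sample(c(rep(TRUE, k), rep(FALSE, n - k)))
}

# categorical draw of n values over named probabilities; in balanced mode the
# realized counts are the randomized rounding of n * probs (expectations are
# unchanged, sampling noise drops to rounding level)
draw_cat <- function(n, probs, balanced) {
  if (n == 0) return(character(0))
  if (!balanced) {
    return(sample(names(probs), n, replace = TRUE, prob = probs))
  }
  x <- n * probs / sum(probs)
  k <- floor(x)
  rem <- n - sum(k)
  if (rem > 0) {
    frac <- x - k
    extra <- sample(seq_along(k), rem, prob = pmax(frac, 1e-12))
    k[extra] <- k[extra] + 1
  }
  sample(rep(names(probs), k))
}

draw_bool <- function(n, p, balanced) {
  if (n == 0) return(logical(0))
  if (!balanced) return(stats::runif(n) < p)
  k <- floor(n * p) + (stats::runif(1) < (n * p - floor(n * p)))
  sample(c(rep(TRUE, k), rep(FALSE, n - k)))
}

# draw per-drink frequency/container categories, cell by cell (theta is
# constant within a wave x school x race x exposure cell)
draw_responses <- function(stu, config, catalog) {
  n <- nrow(stu)
  drinks <- names(config$drink_weights)
  W <- config$drink_weights
  balanced <- config$sampling == "balanced"
  daily_levels <- daily_frequency_levels()
  freq <- matrix("Never", n, length(drinks), dimnames = list(NULL, drinks))
  cont <- matrix(NA_character_, n, length(drinks),
                 dimnames = list(NULL, drinks))
  cells <- split(seq_len(n), list(stu$wave, stu$school_id,
                                  stu$race_ethnicity, stu$high_exposure),
                 drop = TRUE)
  for (idx in cells) {
    theta <- stu$theta[idx[1]]
    r <- theta / (1 + theta)
    daily <- idx[stu$daily[idx]]
    primary <- rep(NA_character_, length(idx))
    names(primary) <- as.character(idx)
    if (length(daily)) {
      primary[as.character(daily)] <- draw_cat(length(daily), W, balanced)
      esc <- draw_cat(length(daily),
                      stats::setNames(c((1 - r)^2, 2 * r * (1 - r), r^2),
                                      daily_levels), balanced)
      freq[cbind(daily, match(primary[as.character(daily)], drinks))] <- esc
    }
    for (d in drinks) {
      q <- 1 - exp(-theta * W[[d]])
      elig <- idx[freq[idx, d] == "Never"]  # not escalated as primary
      sub <- elig[draw_bool(length(elig), q, balanced)]
      freq[sub, d] <- "I drink it but not every day"
      reported <- idx[freq[idx, d] != "Never"]
      if (length(reported)) {
        cont[reported, d] <- draw_cat(length(reported),
                                      config$container_probs[[d]], balanced)
      }
    }
  }
  for (d in drinks) {
    stu[[paste0("freq_", d)]] <- freq[, d]
    stu[[paste0("container_", d)]] <- cont[, d]
  }
  stu
}

# Per-school population race shares: the sample's realized shares with
# multiple/other deflated (the sample over-represents that group) plus small
# per-school noise, renormalized.
population_shares <- function(stu, config) {
  races <- names(config$race_mix)
  schools <- sort(unique(stu$school_id))
  out <- data.frame(school_id = schools, stringsAsFactors = FALSE)
  shares <- matrix(0, length(schools), length(races),
                   dimnames = list(schools, races))
  for (s in schools) {
    tab <- table(factor(stu$race_ethnicity[stu$school_id == s],
                        levels = races))
    shares[s, ] <- as.numeric(tab) / sum(tab)
  }
  pop <- shares
  pop[, "multiple_other"] <- pop[, "multiple_other"] * 0.75
  pop <- pop + matrix(stats::rnorm(length(pop), 0, 0.005), nrow(pop))
  pop[pop < 0.001] <- 0.001
  pop <- pop / rowSums(pop)
  list(sample = cbind(out, as.data.frame(shares)),
       population = cbind(out, as.data.frame(pop)))
}

# integer allocation of n by probabilities, largest-remainder rounding
largest_remainder <- function(n, probs) {
  x <- n * probs / sum(probs)
  k <- floor(x)
  rem <- n - sum(k)
  if (rem > 0) {
    extra <- order(x - k, decreasing = TRUE)[seq_len(rem)]
    k[extra] <- k[extra] + 1
  }
  stats::setNames(as.integer(k), names(probs))
}
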