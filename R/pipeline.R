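#' Run the full consumption-trend pipeline
#'
#' Orchestrates: establishment categorization and zone assignment, zone
#' inventory and high/low exposure classification, survey calorie scoring,
#' low-response wave exclusion, and the four reporting tables (prevalence and
#' calories, overall/by race and by exposure), plus the data series behind the
#' Black/white-by-exposure prevalence figure, and a run manifest.
#'
#' @param survey survey data frame (see [read_survey()]).
#' @param establishments establishment data frame; either `x`/`y` coordinates
#'   (assigned to `zones` by containment) or a pre-assigned `zone_id` column.
#' @param zones a `zone_set` (polygons) or a `school_id`/`zone_id` membership
#'   data frame for geometry-free mode. In geometry-free mode establishments
#'   must arrive pre-assigned.
#' @param catalog a [beverage_catalog()].
#' @param response_rates named vector or data frame of per-wave response
#'   rates.
#' @param min_response_rate waves below this rate are excluded (default 0.5).
#' @param alpha significance level for baseline contrasts (default 0.01).
#' @param baseline baseline wave label (default: first wave surviving
#'   exclusion).
#' @param by_type if `TRUE`, tables 1 and 3 also include per-drink-type
#'   outcomes (five extra model families per stratum); default `FALSE`.
#' @param strict_missing passed to [score_cohort()].
#' @param merge_zone_ids optional character vector of zone ids to combine into
#'   one zone (e.g. when a new school split an existing neighborhood) before
#'   classification.
#' @param seed recorded in the manifest (the pipeline itself is
#'   deterministic).
#' @return list with `table1`, `table2`, `table3`, `table4` (tidy data
#'   frames), `fig1_series`, `exposure`, `inventories`, `scored`, and
#'   `manifest`.
#' @export
run_pipeline <- function(survey, establishments, zones,
                         catalog = default_catalog(), response_rates,
                         min_response_rate = 0.5, alpha = 0.01,
                         baseline = NULL, by_type = FALSE,
                         strict_missing = FALSE, merge_zone_ids = NULL,
                         seed = NA_integer_) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("[", name, "] ", conditionMessage(e), call. = FALSE)
    })
  }
  est <- stage("food_environment", {
    e <- if ("category" %in% names(establishments)) establishments
         else categorize_establishments(establishments)
    if (!("zone_id" %in% names(e)) || anyNA(e$zone_id)) {
      if (!inherits(zones, "zone_set")) {
        stop("establishments lack zone_id and no zone geometries were given")
      }
      e <- assign_establishments(e, zones)
    }
    e
  })
  inv <- stage("food_environment", {
    i <- build_inventories(est, zones)
    if (!is.null(merge_zone_ids)) i <- merge_zones(i, merge_zone_ids)
    i
  })
  exposure <- stage("food_environment", classify_zones(inv))
  membership <- stage("food_environment", {
    if (inherits(zones, "zone_set")) {
      mem <- zone_membership(zones)
    } else {
      stopifnot(all(c("school_id", "zone_id") %in% names(zones)))
      mem <- unique(zones[c("school_id", "zone_id")])
    }
    if (!is.null(merge_zone_ids)) {
      new_id <- setdiff(exposure$zone_id, mem$zone_id)
      mem$zone_id[mem$zone_id %in% merge_zone_ids] <- new_id
    }
    mem
  })

  scored <- stage("scoring", score_cohort(survey, catalog, strict_missing))
  scored <- stage("wave_exclusion", {
    s <- exclude_low_response_waves(scored, response_rates, min_response_rate)
    if (length(unique(s$wave)) < 2) {
      stop("fewer than two waves survive exclusion; no trend to estimate")
    }
    s
  })
  excluded <- attr(scored, "excluded_waves")
  scored <- stage("exposure_join", join_exposure(scored, exposure, membership))

  drinks <- catalog$drink_types
  prev_outcomes <- c(any_drink = "daily_consumer")
  kcal_outcomes <- c(total = "total_kcal")
  if (by_type) {
    prev_outcomes <- c(prev_outcomes,
                       stats::setNames(paste0("daily_", drinks), drinks))
    kcal_outcomes <- c(kcal_outcomes,
                       stats::setNames(paste0("kcal_", drinks), drinks))
  }

  notes <- list()
  fit_set <- function(outcome_map, family, by = NULL) {
    do.call(rbind, lapply(names(outcome_map), function(lab) {
      spec <- model_spec(outcome_map[[lab]], family, baseline = baseline,
                        alpha = alpha)
      rows <- if (is.null(by)) {
        full <- fit_trend_model(scored, spec)
        notes[[paste(lab, family, "full")]] <<-
          attr(full, "convergence_notes")
        race <- stratified_analysis(scored, spec, by = "race")
        rbind(cbind(stratum = "all", as.data.frame(full)),
              do.call(rbind, lapply(names(race), function(nm) {
                cbind(stratum = nm, as.data.frame(race[[nm]]))
              })))
      } else {
        expo <- stratified_analysis(scored, spec, by = "exposure")
        rx <- stratified_analysis(scored, spec, by = c("race", "exposure"))
        rbind(do.call(rbind, lapply(names(expo), function(nm) {
          cbind(stratum = paste0("all:", nm), as.data.frame(expo[[nm]]))
        })),
        do.call(rbind, lapply(names(rx), function(nm) {
          cbind(stratum = nm, as.data.frame(rx[[nm]]))
        })))
      }
      cbind(outcome = lab, rows)
    }))
  }
  table1 <- stage("inference", fit_set(prev_outcomes, "logistic"))
  table2 <- stage("inference", fit_set(prev_outcomes["any_drink"], "logistic",
                                       by = "exposure"))
  table3 <- stage("inference", fit_set(kcal_outcomes, "linear"))
  table4 <- stage("inference", fit_set(kcal_outcomes["total"], "linear",
                                       by = "exposure"))
  fig1 <- table2[table2$stratum %in% c("Black:high", "Black:low",
                                       "white:high", "white:low"),
                 c("stratum", "wave", "estimate", "ci_low", "ci_high",
                   "significant")]

  manifest <- list(
    package_version = as.character(utils::packageVersion("ssbtrends")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = seed,
    alpha = alpha,
    min_response_rate = min_response_rate,
    baseline = if (is.null(baseline)) sort(unique(scored$wave))[1] else baseline,
    excluded_waves = excluded,
    exposure_threshold = attr(exposure, "threshold"),
    n_students_analyzed = nrow(scored),
    input_hashes = list(survey = fnv1a(survey),
                        establishments = fnv1a(establishments),
                        catalog = fnv1a(unclass(catalog))),
    convergence_notes = notes)

  list(table1 = table1, table2 = table2, table3 = table3, table4 = table4,
       fig1_series = fig1, exposure = exposure, inventories = inv,
       scored = scored, manifest = manifest)
}

#' Render a tidy estimate table as markdown
#'
#' One row per stratum, one column per wave, cells formatted as
#' `estimate (ci_low, ci_high)` with a trailing `*` marking a Bonferroni-
#' significant difference from baseline.
#'
#' @param table one of the tidy tables from [run_pipeline()].
#' @param digits digits for the estimates.
#' @return character vector of markdown lines.
#' @export
render_table_markdown <- function(table, digits = 1) {
  fmt <- function(row) {
    sprintf("%.*f (%.*f, %.*f)%s", digits, row$estimate, digits, row$ci_low,
            digits, row$ci_high, if (isTRUE(row$significant)) "*" else "")
  }
  waves <- sort(unique(table$wave))
  keys <- unique(table[c("outcome", "stratum")])
  header <- paste0("| outcome | stratum | ", paste(waves, collapse = " | "),
                   " |")
  sep <- paste0("|", paste(rep("---|", length(waves) + 2), collapse = ""))
  lines <- c(header, sep)
  for (i in seq_len(nrow(keys))) {
    cells <- vapply(waves, function(w) {
      row <- table[table$outcome == keys$outcome[i] &
                     table$stratum == keys$stratum[i] & table$wave == w, ]
      if (nrow(row) == 0) "-" else fmt(row[1, ])
    }, "")
    lines <- c(lines, paste0("| ", keys$outcome[i], " | ", keys$stratum[i],
                             " | ", paste(cells, collapse = " | "), " |"))
  }
  lines
}

#' Write pipeline outputs to a directory
#'
#' Emits the four tidy tables and the figure series as CSV, rendered markdown
#' views of the tables, and the manifest as JSON. Written atomically: files
#' land in a temporary directory first so a failure leaves no partial output.
#'
#' @param result output of [run_pipeline()].
#' @param dir destination directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline_outputs <- function(result, dir) {
  tmp <- tempfile("ssbtrends_out_")
  dir.create(tmp, recursive = TRUE)
  for (nm in c("table1", "table2", "table3", "table4", "fig1_series")) {
    utils::write.csv(result[[nm]], file.path(tmp, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  for (nm in paste0("table", 1:4)) {
    writeLines(render_table_markdown(result[[nm]]),
               file.path(tmp, paste0(nm, ".md")))
  }
  jsonlite::write_json(result$manifest, file.path(tmp, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (f in list.files(tmp)) {
    file.copy(file.path(tmp, f), file.path(dir, f), overwrite = TRUE)
  }
  unlink(tmp, recursive = TRUE)
  invisible(dir)
}

# Rolling polynomial hash of an R object's serialization, as a hex string
# (manifest provenance; not cryptographic)
fnv1a <- function(obj) {
  bytes <- as.double(serialize(obj, NULL, version = 2))
  p <- 2^31 - 1
  idx <- seq_along(bytes)
  # position-weighted checksum, vectorized; weights cycle so products stay
  # exactly representable in double precision
  w1 <- (idx %% 8191) + 1
  w2 <- (idx %% 127) + 1
  h <- (sum(bytes * w1) %% p) * 65536 + (sum(bytes * w2 * w2) %% 65536)
  sprintf("%012.0f", h %% (2^47))
}
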