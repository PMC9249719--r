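#' Score one survey record into daily-consumer status and daily calories
#'
#' Daily calories for each drink type are frequency (times/day) x container
#' size (oz) x calorie density (kcal/oz); the total is the sum over the five
#' drink types. A student is a daily consumer of a drink if the reported
#' frequency category is at least "1 time per day" -- the definition is
#' categorical, so "I drink it but not every day" contributes calories (at its
#' mapped rate) but never daily-consumer status.
#'
#' @param record a list (or one-row data frame) with a `responses` element:
#'   per drink type a list with `frequency` and `container` labels, either of
#'   which may be `NA`.
#' @param catalog a [beverage_catalog()].
#' @param strict_missing if `TRUE`, a drink with a non-"Never" frequency but a
#'   missing container (or a missing frequency with a reported container) is an
#'   error; the default mirrors the convention of coding non-reporters as
#'   consuming 0 calories from that beverage.
#' @return A list of class `calorie_score` with `per_drink_kcal`, `total_kcal`,
#'   `daily_by_drink` and `daily_consumer`.
#' @export
score_record <- function(record, catalog, strict_missing = FALSE) {
  stopifnot(inherits(catalog, "beverage_catalog"))
  responses <- record$responses
  if (is.null(responses)) stop("malformed record: no responses element")
  extra <- setdiff(names(responses), catalog$drink_types)
  if (length(extra)) {
    stop("record reports unknown drink type(s): ", paste(extra, collapse = ", "))
  }
  per_drink <- stats::setNames(numeric(length(catalog$drink_types)),
                               catalog$drink_types)
  daily <- stats::setNames(logical(length(catalog$drink_types)),
                           catalog$drink_types)
  for (d in catalog$drink_types) {
    resp <- responses[[d]]
    freq <- if (is.null(resp)) NA_character_ else resp$frequency
    cont <- if (is.null(resp)) NA_character_ else resp$container
    if (is.null(freq)) freq <- NA_character_
    if (is.null(cont)) cont <- NA_character_
    times <- map_frequency(freq, catalog)
    if (is.na(times)) {
      if (strict_missing) stop("missing frequency for drink '", d, "'")
      next  # contributes 0 kcal, not a daily consumer of d
    }
    daily[d] <- freq %in% daily_frequency_levels()
    if (times == 0) next  # "Never": no container needed
    if (is.na(cont)) {
      if (strict_missing) stop("missing container for drink '", d, "'")
      daily[d] <- FALSE
      next
    }
    per_drink[d] <- times * serving_kcal(catalog, d, cont)
  }
  structure(list(per_drink_kcal = per_drink,
                 total_kcal = sum(per_drink),
                 daily_by_drink = daily,
                 daily_consumer = any(daily)),
            class = "calorie_score")
}

#' Score a survey cohort
#'
#' Applies [score_record()] to every row of a survey data frame (as read by
#' [read_survey()]) and returns the input with scoring columns appended:
#' `kcal_<drink>` per drink type, `total_kcal`, `daily_<drink>` flags and the
#' any-drink `daily_consumer` flag.
#'
#' @param survey data frame with columns `freq_<drink>` and `container_<drink>`
#'   for each catalog drink type (plus any id/demographic columns, carried
#'   through untouched).
#' @inheritParams score_record
#' @return The input data frame with scoring columns appended.
#' @export
score_cohort <- function(survey, catalog, strict_missing = FALSE) {
  stopifnot(is.data.frame(survey), nrow(survey) >= 1)
  drinks <- catalog$drink_types
  fcols <- paste0("freq_", drinks)
  ccols <- paste0("container_", drinks)
  miss <- setdiff(c(fcols, ccols), names(survey))
  if (length(miss)) stop("survey is missing column(s): ", paste(miss, collapse = ", "))

  out <- survey
  kcal <- matrix(0, nrow(survey), length(drinks),
                 dimnames = list(NULL, drinks))
  daily <- matrix(FALSE, nrow(survey), length(drinks),
                  dimnames = list(NULL, drinks))
  for (j in seq_along(drinks)) {
    d <- drinks[j]
    freq <- as.character(survey[[fcols[j]]])
    cont <- as.character(survey[[ccols[j]]])
    freq[!is.na(freq) & freq == ""] <- NA
    cont[!is.na(cont) & cont == ""] <- NA
    times <- tryCatch(map_frequency(freq, catalog), error = function(e) {
      stop("column ", fcols[j], ": ", conditionMessage(e), call. = FALSE)
    })
    if (strict_missing && any(is.na(times))) {
      stop("missing frequency for drink '", d, "' in row(s) ",
           paste(utils::head(which(is.na(times)), 5), collapse = ", "))
    }
    is_daily <- !is.na(freq) & freq %in% daily_frequency_levels()
    active <- !is.na(times) & times > 0
    if (strict_missing && any(active & is.na(cont))) {
      stop("missing container for drink '", d, "' in row(s) ",
           paste(utils::head(which(active & is.na(cont)), 5), collapse = ", "))
    }
    no_cont <- active & is.na(cont)
    is_daily[no_cont] <- FALSE
    active[no_cont] <- FALSE
    if (any(active)) {
      oz <- catalog$container_ounces[[d]]
      kc <- catalog$kcal_per_ounce[[d]]
      bad <- !(cont[active] %in% names(oz))
      if (any(bad)) {
        stop("catalog has no entry for (", d, ", ",
             paste(unique(cont[active][bad]), collapse = ", "), ") in row(s) ",
             paste(utils::head(which(active)[bad], 5), collapse = ", "))
      }
      kcal[active, j] <- times[active] * oz[cont[active]] * kc[cont[active]]
    }
    daily[, j] <- is_daily
  }
  for (j in seq_along(drinks)) out[[paste0("kcal_", drinks[j])]] <- kcal[, j]
  out$total_kcal <- rowSums(kcal)
  for (j in seq_along(drinks)) out[[paste0("daily_", drinks[j])]] <- daily[, j]
  out$daily_consumer <- rowSums(daily) > 0
  out
}

#' Read a survey CSV
#'
#' Expects one row per student with a header: `wave`, `school_id`,
#' `race_ethnicity` (optionally `student_id`, `gender`) and, per drink type,
#' `freq_<drink>` and `container_<drink>` columns.
#'
#' @param path CSV path (UTF-8).
#' @return A data frame.
#' @export
read_survey <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8",
                        check.names = FALSE)
  need <- c("wave", "school_id", "race_ethnicity")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("survey CSV missing column(s): ",
                         paste(miss, collapse = ", "))
  df
}

#' Write a scored cohort to CSV
#' @param scored output of [score_cohort()].
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_scored <- function(scored, path) {
  utils::write.csv(scored, path, row.names = FALSE)
  invisible(path)
}
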