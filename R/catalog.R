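#' Beverage catalog: drink types, container sizes, calorie density, frequency map
#'
#' A beverage catalog holds the three multiplicands of the calorie score:
#' a frequency-category -> times/day mapping, container sizes in fluid ounces
#' by (drink, container), and calorie density in kcal per fluid ounce by
#' (drink, container).
#'
#' @param drink_types character vector of drink-type labels.
#' @param container_ounces named list: per drink type, a named numeric vector
#'   of fluid ounces per container type. All ounces must be > 0.
#' @param kcal_per_ounce named list with the same shape as `container_ounces`,
#'   giving kcal per fluid ounce (>= 0).
#' @param frequency_map named numeric vector mapping the ordered frequency
#'   categories to times per day. Must contain `"Never" = 0` and be
#'   non-decreasing over the canonical category order.
#'
#' @return An object of class `beverage_catalog`.
#' @export
beverage_catalog <- function(drink_types, container_ounces, kcal_per_ounce,
                             frequency_map) {
  stopifnot(is.character(drink_types), length(drink_types) >= 1)
  if (!setequal(names(container_ounces), drink_types) ||
      !setequal(names(kcal_per_ounce), drink_types)) {
    stop("container_ounces and kcal_per_ounce must be named by drink type")
  }
  for (d in drink_types) {
    oz <- container_ounces[[d]]
    kc <- kcal_per_ounce[[d]]
    if (!setequal(names(kc), names(oz))) {
      stop("container types for kcal_per_ounce and container_ounces disagree for drink '",
           d, "'")
    }
    if (any(oz <= 0)) stop("all container ounces must be > 0 (drink '", d, "')")
    if (any(kc < 0)) stop("kcal per ounce must be >= 0 (drink '", d, "')")
  }
  if (!("Never" %in% names(frequency_map)) || frequency_map[["Never"]] != 0) {
    stop("frequency_map must map \"Never\" to 0")
  }
  ord <- intersect(frequency_levels(), names(frequency_map))
  if (is.unsorted(frequency_map[ord])) {
    stop("frequency_map must be non-decreasing over the ordered categories")
  }
  structure(
    list(drink_types = drink_types,
         container_ounces = lapply(container_ounces, unlist),
         kcal_per_ounce = lapply(kcal_per_ounce, unlist),
         frequency_map = unlist(frequency_map)),
    class = "beverage_catalog")
}

#' Canonical survey frequency categories, least to most frequent
#' @return Character vector of the five frequency-category labels.
#' @export
frequency_levels <- function() {
  c("Never",
    "I drink it but not every day",
    "1 time per day",
    "2-4 times per day",
    "5 or more times per day")
}

#' Frequency categories counted as daily consumption (>= 1 time per day)
#' @return Character vector of daily frequency labels.
#' @export
daily_frequency_levels <- function() {
  c("1 time per day", "2-4 times per day", "5 or more times per day")
}

#' Map a frequency category to times per day
#'
#' The daily-consumer outcome is categorical (any category of at least
#' "1 time per day"); this numeric mapping is used only for the calorie score.
#'
#' @param category frequency-category label(s); `NA` is passed through as `NA`.
#' @param catalog a [beverage_catalog()].
#' @return Numeric times/day, `NA` where the input was missing.
#' @export
map_frequency <- function(category, catalog) {
  stopifnot(inherits(catalog, "beverage_catalog"))
  out <- rep(NA_real_, length(category))
  known <- is.na(category) | category %in% names(catalog$frequency_map)
  if (!all(known)) {
    stop("unknown frequency category: ",
         paste(sQuote(unique(category[!known])), collapse = ", "))
  }
  idx <- !is.na(category)
  out[idx] <- catalog$frequency_map[category[idx]]
  out
}

#' Default beverage catalog (placeholder calorie densities)
#'
#' Ships the five survey drink types with conventional container sizes
#' (glass 8 oz, can 12 oz, bottle 20 oz, pouch 6 oz, juice box 6.75 oz) and
#' typical-product calorie densities. The ounce and kcal/oz entries are a
#' clearly labelled placeholder: analyses of real survey data should supply a
#' catalog derived from an authoritative beverage nutrition database via
#' [read_catalog()]. The frequency mapping uses the standard food-frequency
#' conventions: category midpoint for the bounded category ("2-4 times per
#' day" -> 3) and the lower bound for the open-ended top category ("5 or more
#' times per day" -> 5); sub-daily consumption counts 0.5 times/day.
#'
#' @return A [beverage_catalog()].
#' @export
default_catalog <- function() {
  yaml_path <- system.file("extdata", "default_catalog.yaml",
                           package = "ssbtrends", mustWork = TRUE)
  read_catalog(yaml_path)
}

#' Read a beverage catalog from YAML
#'
#' The file must contain `frequency_map`, `container_ounces` and
#' `kcal_per_ounce` sections; the latter two are maps drink -> container ->
#' value.
#'
#' @param path path to a YAML catalog file.
#' @return A [beverage_catalog()].
#' @export
read_catalog <- function(path) {
  raw <- yaml::read_yaml(path)
  need <- c("frequency_map", "container_ounces", "kcal_per_ounce")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("catalog file missing section(s): ",
                         paste(miss, collapse = ", "))
  beverage_catalog(
    drink_types = names(raw$container_ounces),
    container_ounces = lapply(raw$container_ounces, unlist),
    kcal_per_ounce = lapply(raw$kcal_per_ounce, unlist),
    frequency_map = unlist(raw$frequency_map))
}

#' @export
print.beverage_catalog <- function(x, ...) {
  cat("Beverage catalog:", length(x$drink_types), "drink types\n")
  for (d in x$drink_types) {
    cat("  ", d, ": containers ",
        paste(sprintf("%s (%g oz, %g kcal/oz)", names(x$container_ounces[[d]]),
                      x$container_ounces[[d]], x$kcal_per_ounce[[d]]),
              collapse = ", "), "\n", sep = "")
  }
  cat("  frequency map: ",
      paste(sprintf("%s=%g", names(x$frequency_map), x$frequency_map),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

# kcal of one serving (container) of drink d in container cont
serving_kcal <- function(catalog, drink, container) {
  oz <- catalog$container_ounces[[drink]]
  kc <- catalog$kcal_per_ounce[[drink]]
  if (is.null(oz) || !(container %in% names(oz))) {
    stop("catalog has no entry for (", drink, ", ", container, ")")
  }
  unname(oz[[container]] * kc[[container]])
}
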