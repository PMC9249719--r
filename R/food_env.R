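#' @title Neighborhood food-retail environment
#' @description Build per-attendance-zone establishment inventories and
#'   classify zones as providing high or low exposure to unhealthy food retail
#'   (fast-food restaurants + convenience stores + gas stations with food),
#'   using a strict in-sample-mean threshold on the unhealthy count.
#' @name food_environment
NULL

UNHEALTHY_CATEGORIES <- c("fast_food", "convenience", "gas_station_food")
ALL_CATEGORIES <- c("supermarket_grocery", UNHEALTHY_CATEGORIES)

#' Default industry-code table (NAICS-style codes -> retail category)
#'
#' Maps 445110 to supermarkets/grocery, 722513 to fast-food restaurants,
#' 445120 to convenience stores and 447110 to gas stations with food. The
#' table is plain data and can be replaced wherever a `code_table` argument is
#' accepted.
#'
#' @return data frame with columns `code`, `category`.
#' @export
default_code_table <- function() {
  data.frame(code = c("445110", "722513", "445120", "447110"),
             category = c("supermarket_grocery", "fast_food", "convenience",
                          "gas_station_food"),
             stringsAsFactors = FALSE)
}

#' Categorize establishments by industry code
#'
#' @param establishments data frame with a `category_code` column (and any of
#'   `id`, `x`, `y`, `zone_id`).
#' @param code_table data frame mapping `code` to `category`, see
#'   [default_code_table()].
#' @return the input with a `category` column filled.
#' @export
categorize_establishments <- function(establishments,
                                      code_table = default_code_table()) {
  stopifnot(is.data.frame(establishments), "category_code" %in% names(establishments))
  code <- as.character(establishments$category_code)
  idx <- match(code, as.character(code_table$code))
  if (anyNA(idx)) {
    stop("unknown industry code(s): ",
         paste(unique(code[is.na(idx)]), collapse = ", "))
  }
  establishments$category <- code_table$category[idx]
  establishments
}

#' Assign establishments to attendance zones by point-in-polygon containment
#'
#' Zones must be valid, non-overlapping polygons. Points falling outside every
#' zone are assigned `NA` and reported via the `unassigned` attribute. Points
#' on a shared boundary are assigned to the first containing zone in stable
#' zone-id order.
#'
#' @param establishments data frame with `x`, `y` coordinate columns (planar
#'   or lon/lat treated as planar).
#' @param zones a `zone_set` as returned by [read_zones_geojson()] or
#'   [generate_city()]: a list with `zone_id` and `polygons` (a named list of
#'   two-column coordinate matrices, one ring per zone).
#' @return `establishments` with `zone_id` filled; attribute `unassigned`
#'   holds the row indices left outside all zones.
#' @export
assign_establishments <- function(establishments, zones) {
  stopifnot(is.data.frame(establishments),
            all(c("x", "y") %in% names(establishments)))
  if (anyNA(establishments$x) || anyNA(establishments$y)) {
    stop("establishments must have complete coordinates for zone assignment")
  }
  polys <- zones$polygons[order(zones$zone_id)]
  pts <- cbind(establishments$x, establishments$y)
  zone_id <- rep(NA_character_, nrow(pts))
  for (zid in names(polys)) {
    ring <- polys[[zid]]
    if (!is.matrix(ring) || ncol(ring) != 2 || nrow(ring) < 3) {
      stop("invalid geometry for zone '", zid, "'")
    }
    inside <- mgcv::in.out(rbind(ring, ring[1, , drop = FALSE]), pts)
    clash <- inside & !is.na(zone_id)
    if (any(clash)) {
      stop("overlapping zones contain the same point: '",
           zone_id[which(clash)[1]], "' and '", zid, "'")
    }
    zone_id[inside & is.na(zone_id)] <- zid
  }
  establishments$zone_id <- zone_id
  attr(establishments, "unassigned") <- which(is.na(zone_id))
  establishments
}

#' Build per-zone establishment inventories
#'
#' @param establishments data frame with `zone_id` and `category` columns;
#'   rows with `NA` zone are ignored (they fell outside every zone).
#' @param zones a `zone_set`, or a data frame with `zone_id` (and optionally
#'   `school_ids` comma-separated and `enrollment`) defining the zone universe.
#' @return data frame of class `zone_inventory`: one row per zone with counts
#'   per category, `unhealthy_count`, plus `school_ids`/`enrollment` when
#'   available. Zones with no establishments get all-zero counts.
#' @export
build_inventories <- function(establishments, zones) {
  zdf <- as_zone_frame(zones)
  stopifnot("category" %in% names(establishments),
            "zone_id" %in% names(establishments))
  est <- establishments[!is.na(establishments$zone_id), , drop = FALSE]
  bad <- setdiff(unique(est$category), ALL_CATEGORIES)
  if (length(bad)) stop("unknown establishment category: ",
                        paste(bad, collapse = ", "))
  stray <- setdiff(unique(est$zone_id), zdf$zone_id)
  if (length(stray)) stop("establishments reference unknown zone(s): ",
                          paste(stray, collapse = ", "))
  inv <- zdf
  for (cat in ALL_CATEGORIES) {
    tab <- table(factor(est$zone_id[est$category == cat], levels = zdf$zone_id))
    inv[[cat]] <- as.integer(tab)
  }
  inv$unhealthy_count <- rowSums(inv[UNHEALTHY_CATEGORIES])
  class(inv) <- c("zone_inventory", class(inv))
  inv
}

as_zone_frame <- function(zones) {
  if (is.data.frame(zones)) {
    stopifnot("zone_id" %in% names(zones))
    keep <- intersect(c("zone_id", "school_ids", "enrollment"), names(zones))
    unique(zones[keep])
  } else if (is.list(zones) && !is.null(zones$zone_id)) {
    out <- data.frame(zone_id = zones$zone_id, stringsAsFactors = FALSE)
    if (!is.null(zones$school_ids)) {
      out$school_ids <- vapply(zones$school_ids, paste, "", collapse = ";")
    }
    if (!is.null(zones$enrollment)) out$enrollment <- zones$enrollment
    out
  } else stop("cannot interpret 'zones' as a zone set")
}

#' Merge attendance zones into one combined zone
#'
#' When a new school opens and draws students from several existing zones, the
#' constituent zones are combined into a single zone so that the same
#' neighborhoods are compared over time: establishment counts add, school ids
#' union, enrollment adds.
#'
#' @param inventories a `zone_inventory` data frame.
#' @param zone_ids ids of the zones to merge (all must be present).
#' @param new_id id for the combined zone (default: ids joined with `+`).
#' @return the inventory with the constituent rows replaced by one merged row.
#' @export
merge_zones <- function(inventories, zone_ids,
                        new_id = paste(sort(zone_ids), collapse = "+")) {
  stopifnot(length(zone_ids) >= 1)
  miss <- setdiff(zone_ids, inventories$zone_id)
  if (length(miss)) stop("unknown zone id(s): ", paste(miss, collapse = ", "))
  sel <- inventories$zone_id %in% zone_ids
  merged <- inventories[which(sel)[1], , drop = FALSE]
  merged$zone_id <- new_id
  for (cat in c(ALL_CATEGORIES, "unhealthy_count")) {
    if (cat %in% names(inventories)) merged[[cat]] <- sum(inventories[[cat]][sel])
  }
  if ("school_ids" %in% names(inventories)) {
    ids <- unlist(strsplit(inventories$school_ids[sel], ";", fixed = TRUE))
    merged$school_ids <- paste(sort(unique(ids)), collapse = ";")
  }
  if ("enrollment" %in% names(inventories)) {
    merged$enrollment <- sum(inventories$enrollment[sel])
  }
  out <- rbind(inventories[!sel, , drop = FALSE], merged)
  rownames(out) <- NULL
  class(out) <- class(inventories)
  out
}

#' Classify zones as high/low unhealthy food retail exposure
#'
#' The threshold is the arithmetic in-sample mean of `unhealthy_count` over the
#' zones being classified; a zone is high exposure iff its count is strictly
#' greater than the mean (ties are low exposure). The threshold is computed on
#' the zone set entering the analysis, i.e. after any [merge_zones()].
#'
#' @param inventories a `zone_inventory` data frame (>= 1 zone).
#' @return data frame of class `exposure_map` with `zone_id`,
#'   `unhealthy_count`, `high_exposure` (logical); attribute `threshold`.
#' @export
classify_zones <- function(inventories) {
  if (!is.data.frame(inventories) || nrow(inventories) < 1) {
    stop("need at least one zone to classify")
  }
  thr <- mean(inventories$unhealthy_count)
  out <- data.frame(zone_id = inventories$zone_id,
                    unhealthy_count = inventories$unhealthy_count,
                    high_exposure = inventories$unhealthy_count > thr,
                    stringsAsFactors = FALSE)
  attr(out, "threshold") <- thr
  class(out) <- c("exposure_map", class(out))
  out
}

#' Balance diagnostics for high vs low exposure zones
#'
#' Welch two-sample t-tests comparing enrollment (a proxy for population
#' density) and grocery-store counts between exposure groups, plus descriptive
#' means and standard errors of fast-food and convenience+gas counts by group.
#' Non-significant differences support the use of the unhealthy-count
#' classification on its own.
#'
#' @param inventories a `zone_inventory` data frame.
#' @param exposure an `exposure_map` from [classify_zones()].
#' @return list with `tests` (data frame: measure, t, df, p) and `descriptives`
#'   (data frame: group, n_zones, mean/se of fast-food and convenience+gas
#'   counts). If either exposure group is empty the elements are `NA` with an
#'   explanation attribute.
#' @export
zone_balance_tests <- function(inventories, exposure) {
  hi <- exposure$high_exposure[match(inventories$zone_id, exposure$zone_id)]
  if (anyNA(hi)) stop("exposure map does not cover all zones")
  if (!any(hi) || all(hi)) {
    out <- list(tests = NA, descriptives = NA)
    attr(out, "explanation") <- "one exposure group is empty; diagnostics undefined"
    return(out)
  }
  welch <- function(x) {
    if (all(x[hi] == x[hi][1]) && all(x[!hi] == x[!hi][1]) &&
        x[hi][1] == x[!hi][1]) {
      return(c(t = 0, df = NA, p = 1))  # degenerate identical groups
    }
    tt <- stats::t.test(x[hi], x[!hi])
    c(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
  }
  tests <- list()
  if ("enrollment" %in% names(inventories) && !anyNA(inventories$enrollment)) {
    tests$enrollment <- welch(inventories$enrollment)
  }
  tests$grocery <- welch(inventories$supermarket_grocery)
  tests_df <- data.frame(measure = names(tests),
                         do.call(rbind, tests), row.names = NULL)
  conv_gas <- inventories$convenience + inventories$gas_station_food
  se <- function(x) stats::sd(x) / sqrt(length(x))
  desc <- data.frame(
    group = c("high", "low"),
    n_zones = c(sum(hi), sum(!hi)),
    fast_food_mean = c(mean(inventories$fast_food[hi]),
                       mean(inventories$fast_food[!hi])),
    fast_food_se = c(se(inventories$fast_food[hi]),
                     se(inventories$fast_food[!hi])),
    conv_gas_mean = c(mean(conv_gas[hi]), mean(conv_gas[!hi])),
    conv_gas_se = c(se(conv_gas[hi]), se(conv_gas[!hi])))
  list(tests = tests_df, descriptives = desc)
}

#' Write a zone inventory + exposure classification to CSV
#' @param inventories a `zone_inventory`.
#' @param exposure an `exposure_map` from [classify_zones()].
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
write_zone_classification <- function(inventories, exposure, path) {
  m <- match(inventories$zone_id, exposure$zone_id)
  out <- inventories
  out$threshold <- attr(exposure, "threshold")
  out$high_exposure <- exposure$high_exposure[m]
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
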