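# Minimal GeoJSON I/O for the two dialects the pipeline uses: a
# FeatureCollection of single-ring polygons (attendance zones) and a
# FeatureCollection of points (establishments). Only the subset of the format
# that the pipeline emits is supported; anything else errors loudly.

#' Read attendance zones from GeoJSON
#'
#' Expects a FeatureCollection of Polygon features with `zone_id` and
#' (optionally) `school_ids` and `enrollment` properties. Only single-ring
#' polygons are supported.
#'
#' @param path GeoJSON file path.
#' @return A `zone_set`: list with `zone_id`, `polygons` (named list of
#'   two-column coordinate matrices), `school_ids` (named list of character
#'   vectors) and `enrollment` (named numeric, `NA` where absent).
#' @export
read_zones_geojson <- function(path) {
  g <- jsonlite::read_json(path)
  if (!identical(g$type, "FeatureCollection")) {
    stop("expected a GeoJSON FeatureCollection")
  }
  feats <- g$features
  zone_id <- character(length(feats))
  polys <- vector("list", length(feats))
  schools <- vector("list", length(feats))
  enroll <- rep(NA_real_, length(feats))
  for (i in seq_along(feats)) {
    f <- feats[[i]]
    if (!identical(f$geometry$type, "Polygon")) {
      stop("feature ", i, ": only Polygon geometries are supported")
    }
    rings <- f$geometry$coordinates
    if (length(rings) != 1) stop("feature ", i, ": holes are not supported")
    ring <- do.call(rbind, lapply(rings[[1]], function(xy) {
      as.numeric(unlist(xy)[1:2])
    }))
    # drop the closing vertex GeoJSON requires
    if (nrow(ring) > 1 && all(ring[1, ] == ring[nrow(ring), ])) {
      ring <- ring[-nrow(ring), , drop = FALSE]
    }
    zone_id[i] <- as.character(f$properties$zone_id)
    polys[[i]] <- ring
    sid <- f$properties$school_ids
    schools[[i]] <- if (is.null(sid)) character(0) else as.character(unlist(sid))
    if (!is.null(f$properties$enrollment)) {
      enroll[i] <- as.numeric(f$properties$enrollment)
    }
  }
  if (anyDuplicated(zone_id)) stop("duplicate zone_id in GeoJSON")
  names(polys) <- names(schools) <- names(enroll) <- zone_id
  structure(list(zone_id = zone_id, polygons = polys,
                 school_ids = schools, enrollment = enroll),
            class = "zone_set")
}

#' Write attendance zones to GeoJSON
#' @param zones a `zone_set` (see [read_zones_geojson()]).
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_zones_geojson <- function(zones, path) {
  feats <- lapply(zones$zone_id, function(zid) {
    ring <- zones$polygons[[zid]]
    ring <- rbind(ring, ring[1, , drop = FALSE])  # close the ring
    coords <- list(lapply(seq_len(nrow(ring)), function(i) as.list(ring[i, ])))
    props <- list(zone_id = zid,
                  school_ids = as.list(zones$school_ids[[zid]]))
    if (!is.null(zones$enrollment) && !is.na(zones$enrollment[[zid]])) {
      props$enrollment <- zones$enrollment[[zid]]
    }
    list(type = "Feature",
         geometry = list(type = "Polygon", coordinates = coords),
         properties = props)
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read establishments from CSV
#'
#' Expects columns `id`, `category_code` and either `x`,`y` coordinates or a
#' pre-assigned `zone_id` (geometry-free mode).
#'
#' @param path CSV path.
#' @return data frame.
#' @export
read_establishments <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(category_code = "character"))
  if (!("category_code" %in% names(df))) {
    stop("establishments CSV missing 'category_code'")
  }
  has_xy <- all(c("x", "y") %in% names(df))
  if (!has_xy && !("zone_id" %in% names(df))) {
    stop("establishments need either x/y coordinates or a zone_id column")
  }
  df
}

#' Write establishments to CSV
#' @param establishments data frame.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_establishments <- function(establishments, path) {
  utils::write.csv(establishments, path, row.names = FALSE)
  invisible(path)
}

#' School to zone membership table of a zone set
#' @param zones a `zone_set`.
#' @return data frame with `school_id`, `zone_id`.
#' @export
zone_membership <- function(zones) {
  do.call(rbind, lapply(zones$zone_id, function(zid) {
    sids <- zones$school_ids[[zid]]
    if (!length(sids)) return(NULL)
    data.frame(school_id = sids, zone_id = zid, stringsAsFactors = FALSE)
  }))
}
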