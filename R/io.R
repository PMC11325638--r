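# Readers and writers for the pipeline's on-disk formats. Block groups are
# GeoJSON FeatureCollections (standard lon-lat coordinate order; the
# synthetic planar mode stores km in the same slots and tags the file with
# "crs_tag": "planar_km" — mixing modes across files is a hard error).
# Everything else is plain CSV.

bg_required_properties <- function() {
  c("block_group_id", "county_id", "pct_hispanic", "pct_black",
    "pct_asian_pi", "pct_other", "pct_white", "pct_poverty", "pct_renters",
    "pct_no_vehicle", "pop_density")
}

#' Write block groups to GeoJSON
#'
#' @param block_groups Block-group tibble with `geometry` list-column.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_blockgroups <- function(block_groups, path) {
  check_columns(block_groups, c(bg_required_properties(), "geometry"),
                "block_groups")
  features <- purrr::pmap(
    list(seq_len(nrow(block_groups))),
    function(i) {
      row <- block_groups[i, ]
      ring <- close_ring(row$geometry[[1]])
      props <- as.list(row[, bg_required_properties()])
      list(
        type = "Feature",
        properties = props,
        geometry = list(
          type = "Polygon",
          coordinates = list(unname(apply(ring, 1,
                                          function(v) as.list(unname(v)),
                                          simplify = FALSE)))
        )
      )
    }
  )
  fc <- list(type = "FeatureCollection",
             crs_tag = attr(block_groups, "crs") %||% "planar_km",
             features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = 10,
                       pretty = FALSE)
  invisible(path)
}

#' Read block groups from GeoJSON
#'
#' Validates that every feature carries the full demographic property set
#' (errors name the feature and the missing property) and that
#' race/ethnicity percentages close to 100 within 0.01.
#'
#' @param path GeoJSON file written by [write_blockgroups()] (or any
#'   FeatureCollection of Polygons with the same properties).
#' @return Block-group tibble with recomputed centroids and areas.
#' @export
read_blockgroups <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s.", path))
  fc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(fc$type, "FeatureCollection")) {
    abort("expected a GeoJSON FeatureCollection.")
  }
  crs <- fc$crs_tag %||% "lonlat"
  rows <- purrr::imap(fc$features, function(f, i) {
    props <- f$properties
    fid <- props$block_group_id %||% sprintf("#%d", i)
    missing <- setdiff(bg_required_properties(), names(props))
    if (length(missing) > 0) {
      abort(sprintf("feature %s is missing property %s.", fid,
                    paste(missing, collapse = ", ")))
    }
    if (!identical(f$geometry$type, "Polygon")) {
      abort(sprintf("feature %s: only Polygon geometries are supported.", fid))
    }
    ring <- t(vapply(f$geometry$coordinates[[1]],
                     function(pt) c(as.numeric(pt[[1]]), as.numeric(pt[[2]])),
                     numeric(2)))
    colnames(ring) <- c("x", "y")
    cen <- ring_centroid(ring)
    out <- as_tibble(props[bg_required_properties()])
    out$cx <- cen[1]; out$cy <- cen[2]
    out$area_km2 <- abs(ring_signed_area(ring))
    out$geometry <- list(ring)
    out
  })
  out <- dplyr::bind_rows(rows)
  closure <- out$pct_hispanic + out$pct_black + out$pct_asian_pi +
    out$pct_other + out$pct_white
  bad <- which(abs(closure - 100) > 0.01)
  if (length(bad) > 0) {
    abort(sprintf("race/ethnicity percentages do not sum to 100 (+/- 0.01) for: %s.",
                  paste(out$block_group_id[bad], collapse = ", ")))
  }
  attr(out, "crs") <- crs
  out
}

#' Write and read facility tables
#'
#' CSV round-trip for facility tables; the `reporting_years` list-column is
#' serialized as a semicolon-separated string.
#'
#' @param facilities Facility tibble.
#' @param path CSV path.
#' @return `write_facilities()`: `path`, invisibly. `read_facilities()`: the
#'   facility tibble.
#' @export
write_facilities <- function(facilities, path) {
  out <- facilities
  if ("reporting_years" %in% names(out)) {
    out$reporting_years <- vapply(out$reporting_years,
                                  function(v) paste(v, collapse = ";"),
                                  character(1))
  }
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_facilities
#' @export
read_facilities <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  if ("reporting_years" %in% names(out)) {
    out$reporting_years <- lapply(strsplit(as.character(out$reporting_years), ";"),
                                  as.integer)
  }
  out
}

#' Write and read release-report tables
#'
#' @param reports Report tibble.
#' @param path CSV path.
#' @return `write_reports()`: `path`, invisibly; `read_reports()`: tibble.
#' @export
write_reports <- function(reports, path) {
  readr::write_csv(reports, path)
  invisible(path)
}

#' @rdname write_reports
#' @export
read_reports <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(date = readr::col_date()))
}

#' Write and read wind tables
#' @param wind Wind tibble from [generate_wind()].
#' @param path CSV path.
#' @return `write_wind()`: `path`, invisibly; `read_wind()`: tibble.
#' @export
write_wind <- function(wind, path) {
  readr::write_csv(wind, path)
  invisible(path)
}

#' @rdname write_wind
#' @export
read_wind <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(date = readr::col_date()))
}

#' Write and read county attribute tables
#' @param counties County tibble (see [select_counties()]).
#' @param path CSV path.
#' @return `write_counties()`: `path`, invisibly; `read_counties()`: tibble.
#' @export
write_counties <- function(counties, path) {
  readr::write_csv(counties, path)
  invisible(path)
}

#' @rdname write_counties
#' @export
read_counties <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
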