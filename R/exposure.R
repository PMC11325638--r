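# Exposure classification: buffer distances are measured from the facility /
# release point to the nearest point of the block-group polygon (a block
# group partially inside the ring counts), while downwind bearings use the
# polygon centroid. Both choices are recorded in the result's metadata and
# switchable via `distance_from`.

bg_distances <- function(block_groups, px, py,
                         distance_from = c("polygon", "centroid"),
                         distance_mode = c("planar", "geodesic")) {
  distance_from <- match.arg(distance_from)
  distance_mode <- match.arg(distance_mode)
  if (distance_from == "centroid") {
    if (distance_mode == "planar") {
      sqrt((block_groups$cx - px)^2 + (block_groups$cy - py)^2)
    } else {
      if (!requireNamespace("geosphere", quietly = TRUE)) {
        abort("geodesic mode requires the 'geosphere' package.")
      }
      geosphere::distGeo(c(px, py),
                         cbind(block_groups$cx, block_groups$cy)) / 1000
    }
  } else {
    if (distance_mode == "planar") {
      point_polys_distance(px, py, block_groups$geometry)
    } else {
      geo_point_polys_distance(px, py, block_groups$geometry)
    }
  }
}

bg_bearing <- function(px, py, block_groups, distance_mode = "planar") {
  if (distance_mode == "planar") {
    bearing_deg(px, py, block_groups$cx, block_groups$cy)
  } else {
    geo_bearing_deg(px, py, block_groups$cx, block_groups$cy)
  }
}

#' Classify block groups relative to air emissions events
#'
#' Assigns each block group one air-exposure label for a hurricane's event
#' set, following the buffer-and-sector design:
#'
#' * **exposed** — within `r_near` km of a regulated facility that reported
#'   an event, and downwind (within `half_width` degrees of the daily
#'   dominant leeward direction) on at least one event day; with
#'   `use_wind = FALSE` (the sensitivity definition) merely within `r_near`
#'   km of an event facility.
#' * **excluded** (upwind) — within `r_near` km of an event facility but
#'   downwind on no event day (wind mode only). Calm or missing wind on all
#'   event days falls here and is logged.
#' * **at_risk** — within `r_near` km of at least one regulated facility and
#'   neither exposed nor upwind-excluded; the primary comparison group.
#' * **unexposed** — between `r_near` and `r_far` km of the nearest
#'   regulated facility.
#' * **excluded** (far) — beyond `r_far` km of every facility.
#'
#' Precedence is exposed > upwind-excluded > at_risk > unexposed. Distances
#' use strict `< r_near`; the sector boundary is inclusive.
#'
#' @param block_groups Block-group tibble (needs `block_group_id`, `cx`,
#'   `cy`, `geometry`).
#' @param facilities Facility tibble (`facility_id`, `x`, `y`).
#' @param events Air events: `facility_id`, `date`. Every event facility
#'   must exist in `facilities` with finite coordinates.
#' @param dominant Daily dominant directions from [daily_dominant()]
#'   (required when `use_wind = TRUE`).
#' @param r_near,r_far Buffer radii, km.
#' @param use_wind Apply the downwind requirement? `FALSE` reproduces the
#'   sensitivity analysis that ignores wind direction.
#' @param half_width Downwind sector half-width, degrees.
#' @param distance_from Measure buffer distance to the `"polygon"` boundary
#'   (default) or the `"centroid"`.
#' @param distance_mode `"planar"` (km coordinates) or `"geodesic"`
#'   (lon/lat, WGS84).
#' @return Tibble: `block_group_id`, `air_label`, `excluded_reason`
#'   (`"upwind"`, `"beyond_r_far"`, or `NA`), `dist_nearest_facility`,
#'   `dist_nearest_event_facility`, `n_event_days_downwind`. Classification
#'   settings are attached as the `"settings"` attribute.
#' @export
classify_air <- function(block_groups, facilities, events, dominant = NULL,
                         r_near = 2, r_far = 10, use_wind = TRUE,
                         half_width = 45,
                         distance_from = c("polygon", "centroid"),
                         distance_mode = c("planar", "geodesic")) {
  distance_from <- match.arg(distance_from)
  distance_mode <- match.arg(distance_mode)
  check_columns(block_groups, c("block_group_id", "cx", "cy", "geometry"),
                "block_groups")
  check_columns(facilities, c("facility_id", "x", "y"), "facilities")
  check_columns(events, c("facility_id", "date"), "events")
  check_number(r_near, "r_near", min = 0, strict_min = TRUE)
  check_number(r_far, "r_far", min = r_near, strict_min = TRUE)
  if (use_wind && is.null(dominant)) {
    abort("`dominant` daily wind directions are required when use_wind = TRUE.")
  }

  unknown <- setdiff(events$facility_id, facilities$facility_id)
  if (length(unknown) > 0) {
    abort(sprintf("event facility not found in `facilities`: %s.",
                  paste(unique(unknown), collapse = ", ")))
  }
  bad_coord <- facilities$facility_id[!is.finite(facilities$x) |
                                        !is.finite(facilities$y)]
  if (any(events$facility_id %in% bad_coord)) {
    abort(sprintf("event facility has no usable coordinates: %s.",
                  paste(intersect(unique(events$facility_id), bad_coord),
                        collapse = ", ")))
  }

  n_bg <- nrow(block_groups)
  n_fac <- nrow(facilities)
  dist_mat <- matrix(Inf, n_bg, n_fac)
  for (j in seq_len(n_fac)) {
    if (!is.finite(facilities$x[j]) || !is.finite(facilities$y[j])) next
    dist_mat[, j] <- bg_distances(block_groups, facilities$x[j],
                                  facilities$y[j], distance_from,
                                  distance_mode)
  }
  event_fac <- unique(events$facility_id)
  is_event_fac <- facilities$facility_id %in% event_fac

  d_any <- apply(dist_mat, 1, min)
  d_event <- if (any(is_event_fac)) {
    apply(dist_mat[, is_event_fac, drop = FALSE], 1, min)
  } else {
    rep(Inf, n_bg)
  }
  near_event <- d_event < r_near

  # downwind on >= 1 event day, among event facilities within r_near
  n_days_downwind <- integer(n_bg)
  calm_only <- rep(FALSE, n_bg)
  if (use_wind && nrow(events) > 0) {
    ev_days <- dplyr::distinct(events[, c("facility_id", "date")])
    for (k in seq_len(nrow(ev_days))) {
      j <- match(ev_days$facility_id[k], facilities$facility_id)
      dir <- nearest_point_direction(facilities$x[j], facilities$y[j],
                                     dominant, ev_days$date[k])
      in_ring <- dist_mat[, j] < r_near
      if (!any(in_ring)) next
      if (dir$calm) {
        calm_only[in_ring] <- calm_only[in_ring] | TRUE
        next
      }
      b <- bg_bearing(facilities$x[j], facilities$y[j],
                      block_groups[in_ring, , drop = FALSE], distance_mode)
      dw <- is_downwind(dir$direction_deg, b, half_width)
      n_days_downwind[in_ring] <- n_days_downwind[in_ring] + as.integer(dw)
    }
  }

  exposed <- if (use_wind) near_event & n_days_downwind > 0 else near_event
  upwind_excluded <- use_wind & near_event & !exposed
  at_risk <- d_any < r_near & !exposed & !upwind_excluded
  unexposed <- !exposed & !upwind_excluded & !at_risk & d_any <= r_far
  far_excluded <- !exposed & !upwind_excluded & !at_risk & !unexposed

  label <- dplyr::case_when(
    exposed ~ "exposed",
    upwind_excluded ~ "excluded",
    at_risk ~ "at_risk",
    unexposed ~ "unexposed",
    TRUE ~ "excluded"
  )
  reason <- dplyr::case_when(
    upwind_excluded ~ "upwind",
    far_excluded ~ "beyond_r_far",
    TRUE ~ NA_character_
  )
  n_calm_upwind <- sum(upwind_excluded & calm_only & n_days_downwind == 0)
  if (n_calm_upwind > 0) {
    inform(sprintf(
      "%d block group(s) near an event facility saw only calm event days and were treated as not downwind.",
      n_calm_upwind))
  }

  out <- tibble(
    block_group_id = block_groups$block_group_id,
    air_label = label,
    excluded_reason = reason,
    dist_nearest_facility = ifelse(is.finite(d_any), d_any, NA_real_),
    dist_nearest_event_facility = ifelse(is.finite(d_event), d_event, NA_real_),
    n_event_days_downwind = n_days_downwind
  )
  attr(out, "settings") <- list(r_near = r_near, r_far = r_far,
                                use_wind = use_wind, half_width = half_width,
                                distance_from = distance_from,
                                distance_mode = distance_mode)
  out
}

#' Classify block groups relative to land/water releases
#'
#' A block group is **exposed** when within `r_near` km of at least one
#' geocoded release, **unexposed** when the nearest release lies between
#' `r_near` and `r_far` km, and **excluded** beyond `r_far` km of every
#' release. Reports without finite coordinates are dropped first and their
#' count recorded in the `"dropped_ungeocoded"` attribute.
#'
#' @param block_groups Block-group tibble.
#' @param releases Tibble of release locations (`x`, `y`).
#' @inheritParams classify_air
#' @return Tibble: `block_group_id`, `landwater_label`,
#'   `dist_nearest_release`.
#' @export
classify_landwater <- function(block_groups, releases, r_near = 2, r_far = 10,
                               distance_from = c("polygon", "centroid"),
                               distance_mode = c("planar", "geodesic")) {
  distance_from <- match.arg(distance_from)
  distance_mode <- match.arg(distance_mode)
  check_columns(block_groups, c("block_group_id", "cx", "cy", "geometry"),
                "block_groups")
  check_columns(releases, c("x", "y"), "releases")
  check_number(r_near, "r_near", min = 0, strict_min = TRUE)
  check_number(r_far, "r_far", min = r_near, strict_min = TRUE)

  geocoded <- is.finite(releases$x) & is.finite(releases$y)
  n_dropped <- sum(!geocoded)
  releases <- releases[geocoded, , drop = FALSE]

  n_bg <- nrow(block_groups)
  d <- rep(Inf, n_bg)
  for (j in seq_len(nrow(releases))) {
    dj <- bg_distances(block_groups, releases$x[j], releases$y[j],
                       distance_from, distance_mode)
    d <- pmin(d, dj)
  }
  label <- dplyr::case_when(
    d < r_near ~ "exposed",
    d <= r_far ~ "unexposed",
    TRUE ~ "excluded"
  )
  out <- tibble(
    block_group_id = block_groups$block_group_id,
    landwater_label = label,
    dist_nearest_release = ifelse(is.finite(d), d, NA_real_)
  )
  attr(out, "settings") <- list(r_near = r_near, r_far = r_far,
                                distance_from = distance_from,
                                distance_mode = distance_mode)
  attr(out, "dropped_ungeocoded") <- n_dropped
  out
}
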