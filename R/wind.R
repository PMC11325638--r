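#' Absolute wind speed from zonal and meridional components
#'
#' @param u Zonal wind, m/s, eastward positive.
#' @param v Meridional wind, m/s, northward positive.
#' @return `sqrt(u^2 + v^2)`, m/s.
#' @export
#' @examples
#' wind_speed(3, 4) # 5
wind_speed <- function(u, v) {
  if (any(!is.finite(u)) || any(!is.finite(v))) {
    abort("`u` and `v` must be finite.")
  }
  sqrt(u^2 + v^2)
}

#' Leeward angle: the direction the wind blows toward
#'
#' `atan2(v/ws, u/ws) * 180 / pi`, normalized to `[0, 360)`. The convention
#' is mathematical: degrees counterclockwise from east, consistent with
#' [bearing_deg()] so that downwind comparisons need no conversion. Calm
#' point-hours (`ws == 0`) have no direction and return `NA`.
#'
#' @inheritParams wind_speed
#' @return Degrees in `[0, 360)`, or `NA` where calm.
#' @export
#' @examples
#' leeward_angle(1, 0)  # 0: blowing toward east
#' leeward_angle(0, 2)  # 90: toward north
#' leeward_angle(0, 0)  # NA: calm
leeward_angle <- function(u, v) {
  ws <- wind_speed(u, v)
  out <- (atan2(v, u) * 180 / pi) %% 360
  out[ws == 0] <- NA_real_
  out
}

#' Median direction of a day's observations
#'
#' The daily predominant direction is the arithmetic median of the
#' non-calm leeward angles, in degrees: for an odd count the middle sorted
#' value, for an even count the mean of the two middle values. The median is
#' taken on raw degree values, so angle sets straddling the 0/360 wrap are
#' summarized literally (e.g. `c(350, 0, 10)` has median 10, not 0); see
#' [circular_median_direction()] for the wrap-aware alternative.
#'
#' @param angles Numeric vector of angles in degrees; `NA`s (calm) are
#'   removed first.
#' @return Median angle in `[0, 360)`, or `NA` if no non-calm observation.
#' @export
#' @examples
#' median_direction(c(10, 20, 30)) # 20
#' median_direction(c(0, 90))      # 45
median_direction <- function(angles) {
  angles <- angles[!is.na(angles)]
  if (length(angles) == 0) return(NA_real_)
  median(angles %% 360)
}

#' @rdname median_direction
#' @details `circular_median_direction()` minimizes the sum of circular
#'   distances over candidate angles (observed values and antipodal
#'   midpoints), returning the circular median.
#' @export
circular_median_direction <- function(angles) {
  angles <- angles[!is.na(angles)] %% 360
  if (length(angles) == 0) return(NA_real_)
  if (length(angles) == 1) return(angles)
  cand <- sort(unique(c(angles, (angles + 180) %% 360)))
  cost <- vapply(cand, function(a) sum(circular_diff(a, angles)), numeric(1))
  cand[which.min(cost)]
}

#' Daily dominant wind directions per grid point
#'
#' Reduces an hourly wind field to one predominant direction per grid point
#' per day: calm hours are removed, then the (arithmetic or circular) median
#' of the hourly leeward angles is taken. Point-days with no non-calm hour
#' are flagged calm.
#'
#' @param wind Wind tibble from [generate_wind()] (or the same columns:
#'   `point_id`, `x`, `y`, `date`, `hour`, `u`, `v`).
#' @param method `"arithmetic"` (default) or `"circular"` median.
#' @return Tibble: `point_id`, `x`, `y`, `date`, `direction_deg`, `calm`.
#' @export
daily_dominant <- function(wind, method = c("arithmetic", "circular")) {
  method <- match.arg(method)
  check_columns(wind, c("point_id", "x", "y", "date", "u", "v"), "wind")
  med <- if (method == "arithmetic") median_direction else circular_median_direction
  wind |>
    dplyr::mutate(angle = leeward_angle(.data$u, .data$v)) |>
    dplyr::group_by(.data$point_id, .data$x, .data$y, .data$date) |>
    dplyr::summarise(direction_deg = med(.data$angle), .groups = "drop") |>
    dplyr::mutate(calm = is.na(.data$direction_deg)) |>
    dplyr::arrange(.data$point_id, .data$date)
}

#' Dominant direction at the grid point nearest a location
#'
#' @param x,y Event location.
#' @param dominant Output of [daily_dominant()].
#' @param date Date of interest.
#' @return One-row tibble (`point_id`, `direction_deg`, `calm`); distance
#'   ties go to the lowest `point_id`.
#' @export
nearest_point_direction <- function(x, y, dominant, date) {
  check_columns(dominant, c("point_id", "x", "y", "date", "direction_deg", "calm"),
                "dominant")
  day <- dominant[dominant$date == as.Date(date), , drop = FALSE]
  if (nrow(day) == 0) {
    abort(sprintf("no wind data available for date %s.", format(as.Date(date))))
  }
  d <- sqrt((day$x - x)^2 + (day$y - y)^2)
  day <- day[order(d, day$point_id), , drop = FALSE]
  day[1, c("point_id", "direction_deg", "calm")]
}

#' Is a target downwind of a source?
#'
#' A target is downwind when the bearing from the source to the target lies
#' within `half_width` degrees (default 45, i.e. a 90-degree sector) of the
#' leeward direction, boundary inclusive, with circular wrap-around.
#'
#' @param direction_deg Leeward direction in degrees (math convention);
#'   `NA` (calm) is never downwind.
#' @param bearing Bearing from source to target, same convention.
#' @param half_width Sector half-width in degrees.
#' @return Logical vector.
#' @export
#' @examples
#' is_downwind(0, 30)   # TRUE
#' is_downwind(0, 46)   # FALSE
#' is_downwind(350, 20) # TRUE: wraps across 0
is_downwind <- function(direction_deg, bearing, half_width = 45) {
  out <- circular_diff(direction_deg, bearing) <= half_width
  out[is.na(direction_deg)] <- FALSE
  out
}
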