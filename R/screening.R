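#' Construct a study period
#'
#' @param label Period label, e.g. `"hurricane"`, `"reference_2004"`.
#' @param start,end Inclusive start and end dates.
#' @param year Calendar year the period belongs to (defaults to the start
#'   year).
#' @return One-row tibble with `label`, `start`, `end`, `year`.
#' @export
#' @examples
#' study_period("hurricane", "2005-09-22", "2005-10-02")
study_period <- function(label, start, end, year = NULL) {
  start <- as.Date(start); end <- as.Date(end)
  if (is.na(start) || is.na(end)) abort("`start` and `end` must be valid dates.")
  if (start > end) abort("`start` must be on or before `end`.")
  tibble(label = label, start = start, end = end,
         year = as.integer(year %||% format(start, "%Y")))
}

#' Hurricane study windows
#'
#' The three hurricane analysis windows used in real-data mode: each begins
#' two days before landfall and ends one week after the storm dissipated or
#' left the state, giving 11-day windows for Rita and Ike and a 14-day window
#' for Harvey.
#'
#' @return Tibble with `hurricane`, `label`, `start`, `end`, `year`.
#' @export
hurricane_windows <- function() {
  dplyr::bind_rows(
    dplyr::mutate(study_period("hurricane", "2005-09-22", "2005-10-02"),
                  hurricane = "rita"),
    dplyr::mutate(study_period("hurricane", "2008-09-11", "2008-09-21"),
                  hurricane = "ike"),
    dplyr::mutate(study_period("hurricane", "2017-08-23", "2017-09-05"),
                  hurricane = "harvey")
  )[, c("hurricane", "label", "start", "end", "year")]
}

#' Screening rules for land/water release reports
#'
#' Bundles the configurable code lists used by [filter_landwater()]. The
#' defaults are the package's standard screen (see [landwater_codes()]); the
#' air-keyword list is configurable because the vocabulary marking
#' misfiled air releases ("flaring", "scrubber", "atmosphere") is open-ended.
#'
#' @param allowed_causes,excluded_causes,allowed_types,excluded_types
#'   Character vectors of cause/source-type codes.
#' @param air_keywords Words whose presence in a description marks the report
#'   as an air release (whole-word, case-insensitive match).
#' @return Object of class `landwater_rules`.
#' @export
landwater_rules <- function(allowed_causes = landwater_codes()$allowed_causes,
                            excluded_causes = landwater_codes()$excluded_causes,
                            allowed_types = landwater_codes()$allowed_types,
                            excluded_types = landwater_codes()$excluded_types,
                            air_keywords = c("flaring", "scrubber", "atmosphere")) {
  structure(list(allowed_causes = tolower(allowed_causes),
                 excluded_causes = tolower(excluded_causes),
                 allowed_types = tolower(allowed_types),
                 excluded_types = tolower(excluded_types),
                 air_keywords = tolower(air_keywords)),
            class = "landwater_rules")
}

#' Screen land/water release reports
#'
#' Applies the inclusion/exclusion rules to land/water reports: a report is
#' retained only if its cause is whitelisted and not blacklisted, its source
#' type is whitelisted and not an aircraft/railroad, its description contains
#' no air-release keyword, and it is not a status update. Codes outside the
#' whitelists are excluded conservatively and logged as unrecognized. Each
#' excluded report is logged with the first rule that fired, in the fixed
#' order: update report, excluded cause, excluded source type, unrecognized
#' cause, unrecognized source type, air keyword.
#'
#' @param reports Report tibble; all rows must have `medium == "land_water"`.
#' @param rules A [landwater_rules()] object.
#' @return The retained reports, with the exclusion log attached as the
#'   `"exclusions"` attribute (retrieve with [exclusion_log()]): a tibble of
#'   `report_id` and `rule`.
#' @export
#' @examples
#' r <- tibble::tibble(report_id = c("a", "b"), medium = "land_water",
#'                     cause = c("flood", "derailment"),
#'                     source_type = "storage tank",
#'                     description = "oil spill", is_update = FALSE)
#' kept <- filter_landwater(r)
#' exclusion_log(kept)
filter_landwater <- function(reports, rules = landwater_rules()) {
  check_columns(reports,
                c("report_id", "medium", "cause", "source_type",
                  "description", "is_update"), "reports")
  if (!inherits(rules, "landwater_rules")) {
    abort("`rules` must be a landwater_rules object.")
  }
  if (nrow(reports) > 0 && any(reports$medium != "land_water")) {
    abort("filter_landwater() only screens land/water reports; filter `medium` first.")
  }

  cause <- tolower(trimws(reports$cause %||% character()))
  type <- tolower(trimws(reports$source_type))
  desc <- tolower(reports$description)
  desc[is.na(desc)] <- ""
  kw_pattern <- paste0("\\b(", paste(rules$air_keywords, collapse = "|"), ")\\b")

  rule <- rep(NA_character_, nrow(reports))
  fire <- function(cond, label) {
    hit <- is.na(rule) & cond
    rule[hit] <<- label
    invisible(NULL)
  }
  fire(reports$is_update %in% TRUE, "update report")
  fire(cause %in% rules$excluded_causes, "excluded cause")
  fire(type %in% rules$excluded_types, "excluded source type")
  fire(!(cause %in% rules$allowed_causes), "unrecognized cause")
  fire(!(type %in% rules$allowed_types), "unrecognized source type")
  fire(stringr::str_detect(desc, kw_pattern), "air keyword")

  retained <- reports[is.na(rule), , drop = FALSE]
  exclusions <- tibble(report_id = reports$report_id[!is.na(rule)],
                       rule = rule[!is.na(rule)])
  attr(retained, "exclusions") <- exclusions
  retained
}

#' Retrieve the exclusion log attached by a screening step
#' @param x A tibble returned by [filter_landwater()].
#' @return Tibble of `report_id` and `rule`.
#' @export
exclusion_log <- function(x) {
  attr(x, "exclusions") %||% tibble(report_id = character(), rule = character())
}

n_weekend_days <- function(start, end) {
  d <- seq(start, end, by = "day")
  sum(format(d, "%u") %in% c("6", "7")) # Sat, Sun
}

#' Build a matched reference period
#'
#' Finds the business-as-usual window in `target_year` that matches a
#' hurricane window: identical length, identical weekday and weekend-day
#' counts (weekend = Saturday and Sunday), with the start date as close as
#' possible to the hurricane window's month-day. Ties between an earlier and
#' a later equally close start are broken towards the earlier start. A
#' qualifying window always exists within a +/- 6 day shift because weekday
#' patterns recur weekly.
#'
#' @param hurricane A one-row study-period tibble (see [study_period()]).
#' @param target_year Year for the reference window; must differ from the
#'   hurricane year.
#' @return A one-row study-period tibble labelled
#'   `"reference_<target_year>"`.
#' @export
#' @examples
#' rita <- study_period("hurricane", "2005-09-22", "2005-10-02")
#' build_reference_period(rita, 2004) # starts September 23
build_reference_period <- function(hurricane, target_year) {
  check_columns(hurricane, c("start", "end", "year"), "hurricane")
  if (nrow(hurricane) != 1) abort("`hurricane` must be a single period.")
  check_number(target_year, "target_year", integerish = TRUE)
  if (target_year == hurricane$year) {
    abort("`target_year` must differ from the hurricane year.")
  }
  len <- as.integer(hurricane$end - hurricane$start)
  target_weekend <- n_weekend_days(hurricane$start, hurricane$end)
  base_start <- as.Date(sprintf("%d-%s", target_year,
                                format(hurricane$start, "%m-%d")))
  shifts <- c(0, as.vector(rbind(-(1:6), 1:6))) # 0, -1, 1, -2, 2, ...
  for (k in shifts) {
    s <- base_start + k
    e <- s + len
    if (n_weekend_days(s, e) == target_weekend) {
      return(study_period(sprintf("reference_%d", target_year), s, e,
                          year = target_year))
    }
  }
  abort("no qualifying reference window found within a 6-day shift.") # unreachable
}

#' Sample random comparison days
#'
#' Draws, uniformly without replacement, as many days from `target_year` as
#' the hurricane window contains, excluding the supplied dates (typically
#' the matched reference window) from the pool. The day of the week is not
#' considered.
#'
#' @param hurricane One-row study-period tibble.
#' @param target_year Year to sample from.
#' @param excluded Dates removed from the sampling pool.
#' @param seed Integer seed.
#' @return Sorted vector of Dates.
#' @export
sample_random_days <- function(hurricane, target_year, excluded = as.Date(character()),
                               seed = 1) {
  check_columns(hurricane, c("start", "end"), "hurricane")
  check_number(target_year, "target_year", integerish = TRUE)
  n_days <- as.integer(hurricane$end - hurricane$start) + 1L
  pool <- seq(as.Date(sprintf("%d-01-01", target_year)),
              as.Date(sprintf("%d-12-31", target_year)), by = "day")
  pool <- pool[!pool %in% as.Date(excluded)]
  if (length(pool) < n_days) {
    abort(sprintf("sampling pool has %d days but %d are required.",
                  length(pool), n_days))
  }
  with_seed(derive_seed(seed, 7), sort(sample(pool, n_days)))
}

#' Select study counties
#'
#' A county enters the study area if it was FEMA-designated for assistance,
#' had at least one regulated facility, and was at risk of a contaminant
#' release: cumulative hurricane-window rainfall above `rain_threshold_mm`,
#' or peak sustained wind at the population mean center of at least
#' `wind_threshold_knots`, or at least `facility_threshold` regulated
#' facilities. The thresholds parameterize the storm-specific resolved
#' values (rain 141/127/440 mm for the three storms; wind 64 knots;
#' 24 facilities).
#'
#' @param counties Tibble with `county_id`, `fema_designated`,
#'   `n_regulated_facilities`, `cumulative_rain_mm`, `peak_wind_knots`.
#' @param rain_threshold_mm,wind_threshold_knots,facility_threshold Positive
#'   thresholds.
#' @return Character vector of included county ids.
#' @export
select_counties <- function(counties, rain_threshold_mm = 141,
                            wind_threshold_knots = 64,
                            facility_threshold = 24) {
  check_columns(counties,
                c("county_id", "fema_designated", "n_regulated_facilities",
                  "cumulative_rain_mm", "peak_wind_knots"), "counties")
  check_number(rain_threshold_mm, "rain_threshold_mm", min = 0, strict_min = TRUE)
  check_number(wind_threshold_knots, "wind_threshold_knots", min = 0, strict_min = TRUE)
  check_number(facility_threshold, "facility_threshold", min = 0, strict_min = TRUE)
  keep <- counties$fema_designated &
    counties$n_regulated_facilities >= 1 &
    (counties$cumulative_rain_mm > rain_threshold_mm |
       counties$peak_wind_knots >= wind_threshold_knots |
       counties$n_regulated_facilities >= facility_threshold)
  counties$county_id[keep]
}

#' Tag reports with their study period
#'
#' Assigns each report the label of the period containing its date; reports
#' outside every period get `NA` and are dropped from downstream
#' comparisons. Periods must not overlap.
#'
#' @param reports Report tibble with a `date` column.
#' @param periods Study-period tibble (`label`, `start`, `end`).
#' @return `reports` with added `period_label` column.
#' @export
assign_period <- function(reports, periods) {
  check_columns(reports, "date", "reports")
  check_columns(periods, c("label", "start", "end"), "periods")
  if (nrow(periods) > 1) {
    p <- periods[order(periods$start), ]
    if (any(p$start[-1] <= p$end[-nrow(p)])) {
      abort("study periods overlap; periods must be disjoint.")
    }
  }
  label <- rep(NA_character_, nrow(reports))
  d <- as.Date(reports$date)
  for (i in seq_len(nrow(periods))) {
    hit <- !is.na(d) & d >= periods$start[i] & d <= periods$end[i]
    label[hit] <- periods$label[i]
  }
  reports$period_label <- label
  reports
}
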