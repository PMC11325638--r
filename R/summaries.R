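#' Summarize excess air emissions events
#'
#' The descriptive layer for air events: per study period it tabulates event
#' counts and released pounds by facility category and by contaminant group,
#' cause-code shares, mean (min, max) pounds per event, and mean (min, max)
#' events per reporting facility. All arithmetic is unrounded; the print
#' method applies the display convention (pounds to the nearest integer,
#' events per facility to one decimal).
#'
#' Events are joined to `facilities` for their category; events whose
#' facility is absent from the facility table must carry a manually assigned
#' category in a `category` column of `events`. A contaminant group released
#' in several events contributes one count per event, so group counts can
#' exceed the event total.
#'
#' @param events Air report tibble (rows with `medium == "air"`), already
#'   period-tagged by [assign_period()] (untagged rows are dropped), with
#'   `lbs_*` mass columns.
#' @param facilities Facility tibble (`facility_id`, `category`).
#' @param periods Optional study-period tibble; when supplied,
#'   [assign_period()] is applied first.
#' @return An object of class `air_summary`: a list of tibbles `overall`
#'   (per period: `n_events`, `total_lbs`, mean/min/max pounds per event,
#'   `n_facilities`, mean/min/max events per facility), `by_facility_type`,
#'   `by_pollutant`, and `by_cause` (with percentage shares).
#' @export
summarize_air <- function(events, facilities, periods = NULL) {
  check_columns(events, c("report_id", "medium", "facility_id", "date"),
                "events")
  check_columns(facilities, c("facility_id", "category"), "facilities")
  if (!is.null(periods)) events <- assign_period(events, periods)
  check_columns(events, "period_label", "events")

  events <- events[events$medium == "air" & !is.na(events$period_label), ,
                   drop = FALSE]
  keys <- names(pollutant_group_keys())
  mass_cols <- paste0("lbs_", keys)
  present <- intersect(mass_cols, names(events))
  if (length(present) == 0) abort("`events` has no lbs_* mass columns.")
  mass_mat <- as.matrix(events[, present])
  mass_mat[is.na(mass_mat)] <- 0
  if (any(mass_mat < 0)) abort("negative pollutant mass in `events`.")
  events$event_lbs <- rowSums(mass_mat)

  if (nrow(events) == 0) {
    empty <- tibble(period_label = character())
    return(structure(list(overall = empty, by_facility_type = empty,
                          by_pollutant = empty, by_cause = empty),
                     class = "air_summary"))
  }

  # facility category: inventory record if available, else the manually
  # assigned category carried on the event row
  events$category_join <- facilities$category[
    match(events$facility_id, facilities$facility_id)]
  if ("category" %in% names(events)) {
    events$category_join <- dplyr::coalesce(events$category_join,
                                            events$category)
  }
  if (anyNA(events$category_join)) {
    abort("some events have no facility category; join to `facilities` or supply a `category` column.")
  }

  overall <- events |>
    dplyr::group_by(.data$period_label) |>
    dplyr::summarise(
      n_events = dplyr::n(),
      total_lbs = sum(.data$event_lbs),
      mean_lbs_per_event = mean(.data$event_lbs),
      min_lbs_per_event = min(.data$event_lbs),
      max_lbs_per_event = max(.data$event_lbs),
      n_facilities = dplyr::n_distinct(.data$facility_id),
      .groups = "drop"
    )
  per_fac <- events |>
    dplyr::count(.data$period_label, .data$facility_id,
                 name = "events_per_facility") |>
    dplyr::group_by(.data$period_label) |>
    dplyr::summarise(
      mean_events_per_facility = mean(.data$events_per_facility),
      min_events_per_facility = min(.data$events_per_facility),
      max_events_per_facility = max(.data$events_per_facility),
      .groups = "drop"
    )
  overall <- dplyr::left_join(overall, per_fac, by = "period_label")

  by_type <- events |>
    dplyr::group_by(.data$period_label, category = .data$category_join) |>
    dplyr::summarise(n_events = dplyr::n(),
                     total_lbs = sum(.data$event_lbs), .groups = "drop")

  long <- events |>
    dplyr::select("report_id", "period_label", dplyr::all_of(present)) |>
    tidyr::pivot_longer(dplyr::all_of(present), names_to = "group",
                        names_prefix = "lbs_", values_to = "lbs") |>
    dplyr::filter(!is.na(.data$lbs) & .data$lbs > 0)
  by_pollutant <- long |>
    dplyr::group_by(.data$period_label, .data$group) |>
    dplyr::summarise(n_events = dplyr::n_distinct(.data$report_id),
                     total_lbs = sum(.data$lbs), .groups = "drop")

  by_cause <- events |>
    dplyr::count(.data$period_label, .data$cause, name = "n_events") |>
    dplyr::group_by(.data$period_label) |>
    dplyr::mutate(pct = 100 * .data$n_events / sum(.data$n_events)) |>
    dplyr::ungroup()

  structure(list(overall = overall, by_facility_type = by_type,
                 by_pollutant = by_pollutant, by_cause = by_cause),
            class = "air_summary")
}

#' @method print air_summary
#' @export
print.air_summary <- function(x, ...) {
  cat("Excess air emissions events\n")
  if (nrow(x$overall) == 0) {
    cat("  (no events)\n")
    return(invisible(x))
  }
  disp <- dplyr::mutate(
    x$overall,
    dplyr::across(dplyr::ends_with("lbs_per_event") | dplyr::all_of("total_lbs"),
                  ~ round(.x)),
    dplyr::across(dplyr::ends_with("events_per_facility"), ~ round(.x, 1))
  )
  print(disp)
  cat("\nBy facility type:\n"); print(x$by_facility_type)
  cat("\nBy contaminant group:\n"); print(x$by_pollutant)
  invisible(x)
}

#' Summarize land/water release reports
#'
#' Per-period counts and percentage shares of screened land/water reports by
#' source type and by cause.
#'
#' @param reports Screened land/water report tibble, period-tagged (or
#'   supply `periods`).
#' @param periods Optional study-period tibble.
#' @return Object of class `landwater_summary`: tibbles `overall` (counts
#'   per period), `by_source_type`, `by_cause`.
#' @export
summarize_landwater <- function(reports, periods = NULL) {
  check_columns(reports, c("report_id", "medium", "cause", "source_type"),
                "reports")
  if (!is.null(periods)) reports <- assign_period(reports, periods)
  check_columns(reports, "period_label", "reports")
  reports <- reports[reports$medium == "land_water" &
                       !is.na(reports$period_label), , drop = FALSE]

  overall <- dplyr::count(reports, .data$period_label, name = "n_reports")
  share <- function(col) {
    reports |>
      dplyr::count(.data$period_label, .data[[col]], name = "n_reports") |>
      dplyr::group_by(.data$period_label) |>
      dplyr::mutate(pct = 100 * .data$n_reports / sum(.data$n_reports)) |>
      dplyr::ungroup()
  }
  structure(list(overall = overall,
                 by_source_type = share("source_type"),
                 by_cause = share("cause")),
            class = "landwater_summary")
}

#' @method print landwater_summary
#' @export
print.landwater_summary <- function(x, ...) {
  cat("Land/water release reports\n")
  print(x$overall)
  cat("\nBy source type:\n"); print(x$by_source_type)
  invisible(x)
}

#' Hurricane-to-reference event ratio
#'
#' The headline descriptive contrast: the hurricane-period event count
#' divided by the mean count across reference periods. Periods labelled
#' `"hurricane"` (or starting with `"hurricane"`) are the numerator; periods
#' whose label starts with `"reference"` form the denominator. A zero
#' reference mean flags the ratio as undefined rather than dividing.
#'
#' @param x An `air_summary`, `landwater_summary`, or a tibble of
#'   `period_label` and counts.
#' @param medium `"air"` or `"land_water"` (used for labelling).
#' @return One-row tibble: `medium`, `hurricane_count`, `reference_mean`,
#'   `ratio`, `undefined`.
#' @export
#' @examples
#' counts <- tibble::tibble(period_label = c("hurricane", "reference_2004",
#'                                           "reference_2006"),
#'                          n_events = c(116, 55, 65))
#' period_ratio(counts) # ratio 116 / 60 = 1.93
period_ratio <- function(x, medium = NULL) {
  counts <- if (inherits(x, "air_summary")) {
    medium <- medium %||% "air"
    x$overall[, c("period_label", "n_events")]
  } else if (inherits(x, "landwater_summary")) {
    medium <- medium %||% "land_water"
    dplyr::rename(x$overall, n_events = "n_reports")
  } else {
    check_columns(x, "period_label", "period counts")
    medium <- medium %||% NA_character_
    cnt_col <- intersect(c("n_events", "n_reports", "n"), names(x))[1]
    if (is.na(cnt_col)) abort("`x` needs an n_events / n_reports count column.")
    dplyr::rename(x[, c("period_label", cnt_col)], n_events = dplyr::all_of(cnt_col))
  }
  hur <- counts$n_events[grepl("^hurricane", counts$period_label)]
  ref <- counts$n_events[grepl("^reference", counts$period_label)]
  hur_total <- sum(hur)
  # no reference rows means no reference-period reports were observed; the
  # ratio is then undefined, not an error
  ref_mean <- if (length(ref) == 0) 0 else mean(ref)
  undefined <- ref_mean == 0
  tibble(medium = medium,
         hurricane_count = hur_total,
         reference_mean = ref_mean,
         ratio = if (undefined) NA_real_ else hur_total / ref_mean,
         undefined = undefined)
}
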