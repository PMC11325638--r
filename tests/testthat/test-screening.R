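lw_report <- function(id = "r1", cause = "flood", source_type = "storage tank",
                      description = "oil discharge to ditch",
                      is_update = FALSE) {
  tibble::tibble(report_id = id, medium = "land_water", cause = cause,
                 source_type = source_type, description = description,
                 is_update = is_update)
}

test_that("the land/water screen applies the code lists and keyword rules", {
  reports <- dplyr::bind_rows(
    lw_report("keep1"),                                    # retained
    lw_report("keep2", cause = "equipment failure", source_type = "vessel"),
    lw_report("upd", is_update = TRUE),
    lw_report("derail", cause = "derailment"),
    lw_report("rail", source_type = "railroad"),
    lw_report("odd_cause", cause = "meteor strike"),
    lw_report("odd_type", source_type = "hovercraft"),
    lw_report("flare", description = "unit resumed flaring after power loss"),
    lw_report("scrub", description = "Scrubber malfunction, vented"),
    lw_report("atmo_ok", description = "atmospheric tank overflowed") # not a whole-word match
  )
  kept <- filter_landwater(reports)
  log <- exclusion_log(kept)
  expect_setequal(kept$report_id, c("keep1", "keep2", "atmo_ok"))
  rules <- setNames(log$rule, log$report_id)
  expect_equal(rules[["upd"]], "update report")
  expect_equal(rules[["derail"]], "excluded cause")
  expect_equal(rules[["rail"]], "excluded source type")
  expect_equal(rules[["odd_cause"]], "unrecognized cause")
  expect_equal(rules[["odd_type"]], "unrecognized source type")
  expect_equal(rules[["flare"]], "air keyword")
  expect_equal(rules[["scrub"]], "air keyword") # case-insensitive
})

test_that("screening is idempotent and partitions its input", {
  r <- generate_region(region_spec(4, 4, 1, seed = 2))
  f <- generate_facilities(r, c("petroleum refineries" = 3), seed = 3)
  p <- study_period("hurricane", "2017-08-01", "2017-10-31")
  reports <- generate_reports(f, p, 1, 0, seed = 5, p_air = 0)
  kept <- filter_landwater(reports)
  log <- exclusion_log(kept)
  # partition: every report either retained or excluded exactly once
  expect_equal(sort(c(kept$report_id, log$report_id)), sort(reports$report_id))
  expect_equal(anyDuplicated(log$report_id), 0)
  # idempotence: rescreening retains the same rows (the second pass logs
  # no new exclusions)
  kept2 <- filter_landwater(kept)
  attr(kept, "exclusions") <- NULL
  attr(kept2, "exclusions") <- NULL
  expect_equal(kept2, kept)
  expect_equal(nrow(exclusion_log(filter_landwater(kept))), 0)
})

test_that("reference windows reproduce the printed study windows", {
  rita <- study_period("hurricane", "2005-09-22", "2005-10-02")
  ike <- study_period("hurricane", "2008-09-11", "2008-09-21")
  harvey <- study_period("hurricane", "2017-08-23", "2017-09-05")
  expect_equal(build_reference_period(rita, 2004)$start, as.Date("2004-09-23"))
  expect_equal(build_reference_period(rita, 2004)$end, as.Date("2004-10-03"))
  expect_equal(build_reference_period(rita, 2006)$start, as.Date("2006-09-22"))
  expect_equal(build_reference_period(ike, 2007)$start, as.Date("2007-09-13"))
  expect_equal(build_reference_period(ike, 2007)$end, as.Date("2007-09-23"))
  expect_equal(build_reference_period(ike, 2009)$start, as.Date("2009-09-11"))
  expect_equal(build_reference_period(harvey, 2016)$start, as.Date("2016-08-23"))
  expect_equal(build_reference_period(harvey, 2018)$end, as.Date("2018-09-05"))
})

test_that("every reference window matches length and weekday/weekend counts", {
  n_weekend <- function(s, e) {
    d <- seq(s, e, by = "day")
    sum(format(d, "%u") %in% c("6", "7"))
  }
  set.seed(81)
  for (k in seq_len(1000)) {
    start <- as.Date("1995-01-15") + sample.int(9000, 1)
    len <- sample(4:20, 1)
    hur <- study_period("hurricane", start, start + len)
    target <- as.integer(format(start, "%Y")) + sample(c(-3:-1, 1:3), 1)
    ref <- build_reference_period(hur, target)
    expect_identical(as.integer(ref$end - ref$start), len)
    expect_identical(n_weekend(ref$start, ref$end), n_weekend(hur$start, hur$end))
    expect_identical(ref$year, target)
  }
})

test_that("random comparison days are sampled as specified", {
  rita <- study_period("hurricane", "2005-09-22", "2005-10-02")
  ref <- build_reference_period(rita, 2004)
  excl <- seq(ref$start, ref$end, by = "day")
  days <- sample_random_days(rita, 2004, excluded = excl, seed = 4)
  expect_length(days, 11)
  expect_equal(anyDuplicated(days), 0)
  expect_true(all(format(days, "%Y") == "2004"))
  expect_length(intersect(days, excl), 0)
  expect_identical(days, sample_random_days(rita, 2004, excluded = excl, seed = 4))

  # pool forced to exactly the requested days
  all_2004 <- seq(as.Date("2004-01-01"), as.Date("2004-12-31"), by = "day")
  want <- all_2004[100:110]
  forced <- sample_random_days(rita, 2004, excluded = setdiff(all_2004, want),
                               seed = 1)
  expect_identical(forced, want)
  expect_error(sample_random_days(rita, 2004, excluded = all_2004[-(1:3)],
                                  seed = 1),
               "pool")
})

test_that("county selection implements the inclusion rule", {
  counties <- tibble::tibble(
    county_id = c("a", "b", "c", "d", "e"),
    fema_designated = c(TRUE, TRUE, TRUE, TRUE, FALSE),
    n_regulated_facilities = c(5, 10, 30, 0, 50),
    cumulative_rain_mm = c(150, 100, 0, 200, 500),
    peak_wind_knots = c(0, 50, 0, 70, 80)
  )
  got <- select_counties(counties, 141, 64, 24)
  # a: rain; b: fails all; c: facility count; d: no facilities; e: not designated
  expect_setequal(got, c("a", "c"))
})

test_that("county selection is monotone in rain, wind, and facility count", {
  set.seed(12)
  for (k in 1:200) {
    counties <- tibble::tibble(
      county_id = sprintf("c%02d", 1:12),
      fema_designated = runif(12) < 0.8,
      n_regulated_facilities = rpois(12, 10),
      cumulative_rain_mm = runif(12, 0, 300),
      peak_wind_knots = runif(12, 0, 90)
    )
    base <- select_counties(counties, 141, 64, 24)
    bump <- counties
    j <- sample.int(12, 1)
    col <- sample(c("n_regulated_facilities", "cumulative_rain_mm",
                    "peak_wind_knots"), 1)
    bump[[col]][j] <- bump[[col]][j] + runif(1, 1, 100)
    expect_true(all(base %in% select_counties(bump, 141, 64, 24)))
  }
})

test_that("reports are tagged by containing period and overlaps are rejected", {
  rita <- study_period("hurricane", "2005-09-22", "2005-10-02")
  periods <- dplyr::bind_rows(rita, build_reference_period(rita, 2004))
  reports <- tibble::tibble(
    report_id = c("in", "before", "ref_start"),
    date = as.Date(c("2005-09-22", "2005-09-21", "2004-09-23"))
  )
  tagged <- assign_period(reports, periods)
  expect_equal(tagged$period_label, c("hurricane", NA, "reference_2004"))

  overlapping <- dplyr::bind_rows(
    rita, study_period("other", "2005-10-02", "2005-10-12"))
  expect_error(assign_period(reports, overlapping), "overlap")
})
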