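test_that("air summaries reproduce a printed-style panel after rounding", {
  fx <- table1_fixture(rita_panel(), n_facilities = 42)
  s <- summarize_air(fx$events, fx$facilities)
  ov <- s$overall
  expect_equal(ov$n_events, 115)
  expect_equal(ov$total_lbs, 4589634)
  expect_equal(round(ov$mean_lbs_per_event), 39910)
  expect_equal(ov$n_facilities, 42)
  expect_equal(round(ov$mean_events_per_facility, 1), 2.7)
  # facility-type totals add to the overall total exactly
  expect_equal(sum(s$by_facility_type$total_lbs), ov$total_lbs)
})

test_that("mass and count additivity hold exactly before display rounding", {
  r <- generate_region(region_spec(6, 6, 1, seed = 1))
  f <- generate_facilities(r, c("petroleum refineries" = 2,
                                "petrochemical manufacturing" = 3), seed = 2)
  p <- study_period("hurricane", "2017-08-23", "2017-09-05")
  ev <- generate_reports(f, p, 2, 0, seed = 3, p_air = 1)
  ev <- assign_period(ev, p)
  s <- summarize_air(ev, f)
  mass_cols <- grep("^lbs_", names(ev), value = TRUE)
  total_direct <- sum(as.matrix(ev[, mass_cols]), na.rm = TRUE)
  expect_equal(s$overall$total_lbs, total_direct)
  expect_equal(sum(s$by_facility_type$total_lbs), total_direct)
  expect_equal(sum(s$by_pollutant$total_lbs), total_direct)
  expect_equal(sum(s$by_facility_type$n_events), s$overall$n_events)
  expect_equal(sum(s$by_cause$n_events), s$overall$n_events)

  # permutation invariance: row order never changes any output
  shuffled <- ev[sample.int(nrow(ev)), ]
  s2 <- summarize_air(shuffled, f)
  expect_equal(dplyr::arrange(s2$by_facility_type, category),
               dplyr::arrange(s$by_facility_type, category))
  expect_equal(s2$overall, s$overall)

  # a pollutant group released in several events contributes one count each
  expect_equal(
    s$by_pollutant$n_events[s$by_pollutant$group == "co"],
    sum(ev$lbs_co > 0, na.rm = TRUE))
})

test_that("degenerate air inputs are handled without division by zero", {
  fx <- table1_fixture(rita_panel(), n_facilities = 42)
  none <- fx$events[0, ]
  s <- summarize_air(none, fx$facilities)
  expect_equal(nrow(s$overall), 0)
  bad <- fx$events
  bad$lbs_co[1] <- -5
  expect_error(summarize_air(bad, fx$facilities), "negative")
})

test_that("land/water summaries report per-period source-type shares", {
  reports <- tibble::tibble(
    report_id = sprintf("r%02d", 1:10),
    medium = "land_water",
    cause = "flood",
    source_type = c(rep("storage tank", 3), rep("fixed", 5), rep("vessel", 2)),
    period_label = "hurricane"
  )
  s <- summarize_landwater(reports)
  st <- s$by_source_type
  expect_equal(st$pct[st$source_type == "storage tank"], 30)
  expect_equal(sum(st$n_reports), 10)
})

test_that("the hurricane-to-reference ratio matches the printed arithmetic", {
  counts <- tibble::tibble(
    period_label = c("hurricane", "reference_2004", "reference_2006"),
    n_events = c(116, 55, 65))
  pr <- period_ratio(counts, medium = "air")
  expect_equal(pr$reference_mean, 60)
  expect_equal(round(pr$ratio, 2), 1.93)

  equal <- tibble::tibble(period_label = c("hurricane", "reference_2004"),
                          n_events = c(60, 60))
  expect_equal(period_ratio(equal)$ratio, 1)

  zero <- tibble::tibble(period_label = c("hurricane", "reference_2004"),
                         n_events = c(60, 0))
  expect_true(period_ratio(zero)$undefined)
  expect_true(is.na(period_ratio(zero)$ratio))
})

test_that("estimated period ratios track the generating rates", {
  r <- generate_region(region_spec(4, 4, 1, seed = 2))
  f <- generate_facilities(r, c("petroleum refineries" = 2), seed = 3)
  periods <- dplyr::bind_rows(
    study_period("hurricane", "2000-01-01", "2000-12-30"),
    study_period("reference_a", "2002-01-01", "2002-12-30"),
    study_period("reference_b", "2004-01-01", "2004-12-30"))
  rep <- generate_reports(f, periods, 3, 1, seed = 6, p_air = 0,
                          contamination = 0, air_keyword_frac = 0,
                          update_frac = 0)
  s <- summarize_landwater(rep, periods)
  pr <- period_ratio(s)
  # lambda_h = 2190, lambda_ref = 730 per reference year: 3:1 within noise
  expect_lt(abs(pr$ratio - 3), 0.3)
})
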