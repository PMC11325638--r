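# A deterministic layout: a 16 x 16 km region, one event facility in the
# southwest, wind blowing toward the east, plus a second facility that
# reported nothing. Constructed so each label class is represented.
exposure_layout <- function() {
  region <- generate_region(region_spec(16, 16, 1, seed = 21))
  facilities <- tibble::tibble(
    facility_id = c("ev", "quiet"),
    x = c(3.5, 9.5), y = c(3.5, 2.5)
  )
  events <- tibble::tibble(facility_id = "ev",
                           date = as.Date("2017-08-23"))
  wind <- generate_wind(region, as.Date("2017-08-23"), grid_step_km = 20,
                        regime = "constant", u0 = 2, v0 = 0)
  list(region = region, facilities = facilities, events = events,
       dominant = daily_dominant(wind))
}

test_that("air exposure classes follow the buffer-and-sector rules", {
  lay <- exposure_layout()
  cls <- classify_air(lay$region, lay$facilities, lay$events, lay$dominant)
  lab <- setNames(cls$air_label, cls$block_group_id)
  bg_at <- function(cx, cy) {
    lay$region$block_group_id[lay$region$cx == cx & lay$region$cy == cy]
  }
  # 1 km east of the event facility, downwind -> exposed
  expect_equal(lab[[bg_at(4.5, 3.5)]], "exposed")
  # 1 km west of the same facility, upwind on the only event day -> excluded
  expect_equal(lab[[bg_at(2.5, 3.5)]], "excluded")
  expect_equal(cls$excluded_reason[cls$block_group_id == bg_at(2.5, 3.5)],
               "upwind")
  # near the quiet facility only -> at risk
  expect_equal(lab[[bg_at(9.5, 2.5)]], "at_risk")
  # 5 km north of the event facility, no facility within 2 km -> unexposed
  expect_equal(lab[[bg_at(3.5, 8.5)]], "unexposed")
  # far corner, > 10 km from both facilities -> excluded (beyond the ring)
  expect_equal(lab[[bg_at(15.5, 15.5)]], "excluded")
  expect_equal(cls$excluded_reason[cls$block_group_id == bg_at(15.5, 15.5)],
               "beyond_r_far")
})

test_that("ignoring wind direction can only enlarge the exposed set", {
  lay <- exposure_layout()
  with_wind <- classify_air(lay$region, lay$facilities, lay$events,
                            lay$dominant)
  no_wind <- classify_air(lay$region, lay$facilities, lay$events,
                          use_wind = FALSE)
  ew <- with_wind$block_group_id[with_wind$air_label == "exposed"]
  en <- no_wind$block_group_id[no_wind$air_label == "exposed"]
  expect_true(all(ew %in% en))
  expect_gt(length(en), length(ew)) # the upwind ring joins the exposed set
  # and property-checked over random layouts
  for (seed in 1:5) {
    lay <- random_air_layout(seed)
    w <- classify_air(lay$region, lay$facilities, lay$events, lay$dominant)
    n <- classify_air(lay$region, lay$facilities, lay$events, use_wind = FALSE)
    expect_true(all(w$block_group_id[w$air_label == "exposed"] %in%
                      n$block_group_id[n$air_label == "exposed"]))
  }
})

test_that("an event at a facility without coordinates is a named error", {
  lay <- exposure_layout()
  lay$facilities$x[1] <- NA
  expect_error(
    classify_air(lay$region, lay$facilities, lay$events, lay$dominant),
    "ev")
  expect_error(
    classify_air(lay$region, lay$facilities,
                 tibble::tibble(facility_id = "ghost",
                                date = as.Date("2017-08-23")),
                 lay$dominant),
    "ghost")
})

test_that("calm wind on all event days falls to the upwind-exclusion rule", {
  lay <- exposure_layout()
  calm_wind <- generate_wind(lay$region, as.Date("2017-08-23"),
                             grid_step_km = 20, regime = "constant",
                             u0 = 0, v0 = 0)
  expect_message(
    cls <- classify_air(lay$region, lay$facilities, lay$events,
                        daily_dominant(calm_wind)),
    "calm")
  near_ev <- cls$dist_nearest_event_facility < 2
  expect_true(all(cls$air_label[near_ev] == "excluded"))
})

test_that("land/water exposure uses the release buffers", {
  region <- generate_region(region_spec(1, 24, 1, seed = 9)) # 24 km strip
  releases <- tibble::tibble(x = 0.5, y = 0.5)
  cls <- classify_landwater(region, releases)
  lab <- setNames(cls$landwater_label, cls$block_group_id)
  bg_at <- function(cx) region$block_group_id[region$cx == cx]
  expect_equal(lab[[bg_at(0.5)]], "exposed")    # 0 km
  expect_equal(lab[[bg_at(6.5)]], "unexposed")  # polygon edge at 5.5 km
  expect_equal(lab[[bg_at(15.5)]], "excluded")  # nearest edge 14.5 km
  # ungeocoded releases are dropped and counted
  cls2 <- classify_landwater(region,
                             tibble::tibble(x = c(0.5, NA), y = c(0.5, NA)))
  expect_equal(attr(cls2, "dropped_ungeocoded"), 1)
  expect_equal(cls2$landwater_label, cls$landwater_label)
})

test_that("classification ignores polygon vertex order and orientation", {
  lay <- exposure_layout()
  base <- classify_air(lay$region, lay$facilities, lay$events, lay$dominant)
  scrambled <- lay$region
  set.seed(4)
  scrambled$geometry <- lapply(scrambled$geometry, function(g) {
    ring <- g[-nrow(g), , drop = FALSE]           # open the ring
    k <- sample.int(nrow(ring), 1)
    ring <- ring[c(k:nrow(ring), seq_len(k - 1)), , drop = FALSE] # rotate
    if (runif(1) < 0.5) ring <- ring[rev(seq_len(nrow(ring))), ]  # reverse
    rbind(ring, ring[1, ])
  })
  redo <- classify_air(scrambled, lay$facilities, lay$events, lay$dominant)
  expect_equal(redo$air_label, base$air_label)
  expect_equal(redo$dist_nearest_facility, base$dist_nearest_facility)
})

test_that("the classifier agrees with the brute-force oracle on random layouts", {
  for (seed in 101:110) {
    lay <- random_air_layout(seed)
    got <- classify_air(lay$region, lay$facilities, lay$events, lay$dominant)
    want <- oracle_classify_air(lay$region, lay$facilities, lay$events,
                                lay$dominant)
    expect_identical(got$air_label, want)
  }
})
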