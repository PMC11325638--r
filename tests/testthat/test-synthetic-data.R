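test_that("a 2x2 region is four block groups in one county covering 4 km^2", {
  r <- generate_region(region_spec(2, 2, 1, n_counties = 1, seed = 7))
  expect_equal(nrow(r), 4)
  expect_equal(unique(r$county_id), "county001")
  expect_equal(sum(r$area_km2), 4)
  expect_true(all(vapply(r$geometry, nrow, integer(1)) == 5)) # closed rings
})

test_that("region generation is deterministic in the seed", {
  a <- generate_region(region_spec(6, 5, 1.5, n_counties = 2, seed = 11))
  b <- generate_region(region_spec(6, 5, 1.5, n_counties = 2, seed = 11))
  expect_identical(a, b)
  c <- generate_region(region_spec(6, 5, 1.5, n_counties = 2, seed = 12))
  expect_false(identical(a$pct_hispanic, c$pct_hispanic))
})

test_that("race/ethnicity percentages close to 100 and counties are contiguous", {
  r <- generate_region(region_spec(10, 10, 1, n_counties = 4, seed = 1))
  closure <- r$pct_hispanic + r$pct_black + r$pct_asian_pi + r$pct_other +
    r$pct_white
  expect_true(all(abs(closure - 100) <= 0.01))
  expect_true(all(r[, grep("^pct_", names(r))] >= 0))
  expect_true(all(r$pop_density >= 0))
  expect_equal(dplyr::n_distinct(r$county_id), 4)
  # row-major blocks: county labels are non-decreasing in cell order
  expect_true(!is.unsorted(as.integer(factor(r$county_id,
                                             levels = unique(r$county_id)))))
})

test_that("invalid region specs fail naming the offending field", {
  expect_error(region_spec(0, 3, 1, 1, 1), "n_rows")
  expect_error(region_spec(3, 3, 0, 1, 1), "cell_km")
  expect_error(region_spec(2, 2, 1, n_counties = 5, seed = 1), "n_counties")
})

test_that("facilities respect category counts, bounds, and determinism", {
  r <- generate_region(region_spec(8, 8, 1, seed = 2))
  f <- generate_facilities(r, c("petrochemical manufacturing" = 3), seed = 5)
  expect_equal(nrow(f), 3)
  expect_true(all(f$category == "petrochemical manufacturing"))
  expect_true(all(f$x >= 0 & f$x <= 8 & f$y >= 0 & f$y <= 8))
  f2 <- generate_facilities(r, c("petrochemical manufacturing" = 3), seed = 5)
  expect_identical(f$x, f2$x)

  empty <- generate_facilities(r, c("petroleum refineries" = 0), seed = 5)
  expect_equal(nrow(empty), 0)

  expect_error(generate_facilities(r, c(refinery = 2), seed = 1),
               "petroleum refineries") # error lists the valid categories
})

test_that("zero rates produce no reports and fixed seeds reproduce reports", {
  r <- generate_region(region_spec(5, 5, 1, seed = 2))
  f <- generate_facilities(r, c("petroleum refineries" = 2), seed = 3)
  p <- study_period("hurricane", "2017-08-23", "2017-09-05")
  expect_equal(nrow(generate_reports(f, p, 0, 0, seed = 1)), 0)
  a <- generate_reports(f, p, 0.5, 0.2, seed = 9)
  b <- generate_reports(f, p, 0.5, 0.2, seed = 9)
  expect_identical(a, b)
})

test_that("hurricane:reference event ratio approaches the rate ratio", {
  # long-horizon law-of-large-numbers check; p_air = 0 keeps it count-only
  r <- generate_region(region_spec(3, 3, 1, seed = 2))
  f <- generate_facilities(r, c("petroleum refineries" = 2), seed = 3)
  periods <- dplyr::bind_rows(
    study_period("hurricane", "2001-01-01", "2003-09-27"),   # 1000 days
    study_period("reference_a", "2004-01-01", "2006-09-26")  # 1000 days
  )
  rep <- generate_reports(f, periods, rate_hurricane = 4, rate_reference = 2,
                          seed = 42, p_air = 0, contamination = 0,
                          air_keyword_frac = 0, update_frac = 0)
  tagged <- assign_period(rep, periods)
  n_h <- sum(tagged$period_label == "hurricane")
  n_r <- sum(tagged$period_label == "reference_a")
  expect_gt(n_h + n_r, 10000)
  expect_lt(abs(n_h / n_r - 2), 0.15)
  # Poisson fidelity: counts within 4*sqrt(lambda) of expectation
  expect_lt(abs(n_h - 8000), 4 * sqrt(8000))
  expect_lt(abs(n_r - 4000), 4 * sqrt(4000))
})

test_that("the excluded-code contamination fraction is honoured", {
  r <- generate_region(region_spec(3, 3, 1, seed = 2))
  f <- generate_facilities(r, c("petroleum refineries" = 3), seed = 3)
  p <- study_period("hurricane", "2001-01-01", "2001-12-31")
  rep <- generate_reports(f, p, 3, 0, seed = 7, p_air = 0,
                          contamination = 0.3, air_keyword_frac = 0,
                          update_frac = 0)
  codes <- landwater_codes()
  contaminated <- rep$cause %in% codes$excluded_causes |
    rep$source_type %in% codes$excluded_types
  n <- nrow(rep)
  expect_gt(n, 1000)
  expect_lt(abs(mean(contaminated) - 0.3), 4 * sqrt(0.3 * 0.7 / n))
})

test_that("outcome generation matches its stated model in the limits", {
  r <- generate_region(region_spec(50, 50, 1, seed = 4))
  adj <- build_queen_adjacency(r)
  n <- adj$n
  X <- matrix(rnorm(n), ncol = 1, dimnames = list(NULL, "x"))

  # tau2 = 0: no spatial effect, plain logistic draws at logistic(0) = 0.5
  out0 <- generate_outcomes(X, adj, sim_truth(beta = 0, tau2 = 0), seed = 1)
  expect_true(all(out0$phi == 0))
  expect_lt(abs(mean(out0$y) - 0.5), 4 * sqrt(0.25 / n))

  # maximum-likelihood oracle recovers a known coefficient within 3 SEs
  truth <- sim_truth(beta = log(1.5), rho = 0.8, tau2 = 0.25, intercept = 0)
  out <- generate_outcomes(X, adj, truth, seed = 2)
  ml <- glm(out$y ~ X, family = binomial())
  se <- summary(ml)$coefficients["X", "Std. Error"]
  expect_lt(abs(coef(ml)[["X"]] - log(1.5)), 3 * se)
})

test_that("rho = 1 on a disconnected graph is rejected with guidance", {
  W <- Matrix::bdiag(matrix(c(0, 1, 1, 0), 2), matrix(c(0, 1, 1, 0), 2))
  expect_error(suppressWarnings(
    sample_leroux_effects(W, rho = 1, tau2 = 1, seed = 1)),
    "rho < 1")
})

test_that("spatial effects have the Leroux covariance structure", {
  # at rho = 0 the effects are iid N(0, tau2): check the empirical variance
  W <- Matrix::bdiag(lapply(1:200, function(i) matrix(c(0, 1, 1, 0), 2)))
  phi <- sample_leroux_effects(W, rho = 0, tau2 = 0.5, seed = 3)
  expect_lt(abs(var(phi) - 0.5), 0.15)
  # neighbours are positively correlated at high rho
  r <- generate_region(region_spec(30, 30, 1, seed = 5))
  adj <- build_queen_adjacency(r)
  phi <- sample_leroux_effects(adj$W, rho = 0.95, tau2 = 1, seed = 6)
  Wm <- adj$W
  num <- as.numeric(phi %*% (Wm %*% phi)) / sum(Wm)
  expect_gt(num, 0) # average neighbour product positive
})
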