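#' Pollutant groups used for air emissions masses
#'
#' Individual reported species are aggregated into seven contaminant groups.
#' `pollutant_group_keys()` returns the short column keys (mass columns in
#' report tables are named `lbs_<key>`); `pollutant_group_map()` returns an
#' editable species-to-group lookup used when ingesting per-species tables.
#'
#' @return `pollutant_group_keys()`: named character vector mapping keys to
#'   display names. `pollutant_group_map()`: tibble with `species`, `group`.
#' @export
pollutant_group_keys <- function() {
  c(nmvoc   = "non-methane volatile organic compounds",
    sox     = "sulfur oxides",
    co      = "carbon monoxide",
    nox     = "nitrogen oxides",
    methane = "methane",
    pm      = "particulate matter",
    other   = "other")
}

#' @rdname pollutant_group_keys
#' @export
pollutant_group_map <- function() {
  tibble::tribble(
    ~species,                  ~group,
    "isopentane",              "nmvoc",
    "butane",                  "nmvoc",
    "benzene",                 "nmvoc",
    "toluene",                 "nmvoc",
    "ethylene",                "nmvoc",
    "propylene",               "nmvoc",
    "sulfur dioxide",          "sox",
    "sulfur trioxide",         "sox",
    "carbon monoxide",         "co",
    "nitrogen oxides",         "nox",
    "nitric oxide",            "nox",
    "nitrogen dioxide",        "nox",
    "methane",                 "methane",
    "particulate matter",      "pm",
    "pm10",                    "pm",
    "pm2.5",                   "pm",
    "carbon dioxide",          "other",
    "hydrogen",                "other",
    "hydrogen sulfide",        "other",
    "ammonia",                 "other",
    "acetone",                 "other",
    "lead",                    "other"
  )
}

#' Cause and source-type code lists for land/water release screening
#'
#' `landwater_codes()` returns the whitelists and blacklists applied by
#' [filter_landwater()]: retained causes (flood, hurricane, equipment
#' failure, natural phenomenon, sinking vessel, unknown), retained source
#' types (fixed, mobile, pipeline, storage tank, unknown sheen, vessel),
#' excluded causes (derailment, dumping, explosion, operator error,
#' overpressuring, trespasser), and excluded source types (aircraft,
#' railroad).
#'
#' @return Named list of character vectors.
#' @export
landwater_codes <- function() {
  list(
    allowed_causes = c("flood", "hurricane", "equipment failure",
                       "natural phenomenon", "sinking vessel", "unknown"),
    allowed_types = c("fixed", "mobile", "pipeline", "storage tank",
                      "unknown sheen", "vessel"),
    excluded_causes = c("derailment", "dumping", "explosion",
                        "operator error", "overpressuring", "trespasser"),
    excluded_types = c("aircraft", "railroad")
  )
}

air_cause_codes <- function() c("start-up", "shutdown", "maintenance", "other")

#' Generate synthetic release reports
#'
#' Draws Poisson event counts per facility per day, at `rate_hurricane`
#' events/facility/day inside hurricane-labelled periods and
#' `rate_reference` elsewhere. Each event is an excess air emissions event
#' with probability `p_air` (carrying log-normal per-pollutant-group masses
#' and a cause code) and a land/water release otherwise (carrying cause and
#' source-type codes, a free-text description, and jittered coordinates).
#' To exercise the screening filters, a fraction `contamination` of
#' land/water reports carries an excluded cause or source type, a fraction
#' `air_keyword_frac` of descriptions mentions air-release vocabulary
#' (flaring, scrubber, atmosphere), a fraction `update_frac` is flagged as a
#' status update, and a fraction `ungeocoded_frac` lacks coordinates.
#'
#' @param facilities Facility tibble from [generate_facilities()].
#' @param periods Study-period tibble: columns `label`, `start`, `end`
#'   (Dates) and `year`; see [study_period()].
#' @param rate_hurricane,rate_reference Poisson rates, events per facility
#'   per day (>= 0).
#' @param seed Integer seed.
#' @param p_air Probability an event is an air emissions event.
#' @param contamination Fraction of land/water reports given an excluded
#'   cause/type code.
#' @param air_keyword_frac Fraction of land/water descriptions containing an
#'   air keyword.
#' @param update_frac Fraction of land/water reports flagged `is_update`.
#' @param ungeocoded_frac Fraction of land/water reports without coordinates.
#' @param mass_meanlog,mass_sdlog Log-normal parameters for per-group masses
#'   (pounds); the default heavy tail spans <1 lb to millions of pounds.
#' @return Report tibble: `report_id`, `medium` (`"air"`/`"land_water"`),
#'   `facility_id` (air only), `x`, `y`, `date`, `cause`, `source_type`,
#'   `description`, `is_update`, and `lbs_*` mass columns (air rows only).
#' @export
generate_reports <- function(facilities, periods,
                             rate_hurricane, rate_reference, seed,
                             p_air = 0.5,
                             contamination = 0.2,
                             air_keyword_frac = 0.05,
                             update_frac = 0.1,
                             ungeocoded_frac = 0.05,
                             mass_meanlog = log(1500), mass_sdlog = 2.5) {
  check_columns(facilities, c("facility_id", "x", "y"), "facilities")
  check_columns(periods, c("label", "start", "end"), "periods")
  check_number(rate_hurricane, "rate_hurricane", min = 0)
  check_number(rate_reference, "rate_reference", min = 0)
  check_number(contamination, "contamination", min = 0, max = 1)

  days <- purrr::pmap(periods, function(label, start, end, ...) {
    tibble(period_label = label,
           date = seq(as.Date(start), as.Date(end), by = "day"))
  })
  days <- dplyr::bind_rows(days)
  days$rate <- ifelse(grepl("^hurricane", days$period_label),
                      rate_hurricane, rate_reference)

  if (nrow(facilities) == 0 || nrow(days) == 0 ||
      (rate_hurricane == 0 && rate_reference == 0)) {
    return(empty_reports())
  }

  keys <- names(pollutant_group_keys())
  codes <- landwater_codes()

  out <- with_seed(derive_seed(seed, 3), {
    grid <- tidyr::expand_grid(facility_id = facilities$facility_id,
                               days)
    counts <- rpois(nrow(grid), grid$rate)
    ev <- grid[rep(seq_len(nrow(grid)), counts), c("facility_id", "date")]
    n_ev <- nrow(ev)
    if (n_ev == 0) {
      empty_reports()
    } else {
    ev <- dplyr::left_join(ev, facilities[, c("facility_id", "x", "y")],
                           by = "facility_id")
    is_air <- runif(n_ev) < p_air

    out <- tibble(
      report_id = sprintf("rep%06d", seq_len(n_ev)),
      medium = ifelse(is_air, "air", "land_water"),
      facility_id = ifelse(is_air, ev$facility_id, NA_character_),
      x = ev$x, y = ev$y,
      date = ev$date,
      cause = NA_character_,
      source_type = NA_character_,
      description = NA_character_,
      is_update = FALSE
    )
    for (k in keys) out[[paste0("lbs_", k)]] <- NA_real_

    # --- air events: cause code + 1-3 pollutant groups with log-normal mass
    n_air <- sum(is_air)
    if (n_air > 0) {
      out$cause[is_air] <- sample(air_cause_codes(), n_air, replace = TRUE,
                                  prob = c(0.3, 0.2, 0.05, 0.45))
      group_w <- c(nmvoc = 0.3, sox = 0.1, co = 0.25, nox = 0.2,
                   methane = 0.05, pm = 0.04, other = 0.06)
      air_idx <- which(is_air)
      for (k in keys) out[[paste0("lbs_", k)]][air_idx] <- 0
      for (i in air_idx) {
        n_groups <- sample(1:3, 1)
        gs <- sample(keys, n_groups, prob = group_w[keys])
        out[i, paste0("lbs_", gs)] <-
          as.list(rlnorm(n_groups, mass_meanlog, mass_sdlog))
      }
    }

    # --- land/water reports: codes, description, jittered location
    n_lw <- sum(!is_air)
    if (n_lw > 0) {
      lw <- which(!is_air)
      out$cause[lw] <- sample(codes$allowed_causes, n_lw, replace = TRUE,
                              prob = c(0.25, 0.15, 0.2, 0.1, 0.05, 0.25))
      out$source_type[lw] <- sample(codes$allowed_types, n_lw, replace = TRUE,
                                    prob = c(0.3, 0.1, 0.15, 0.25, 0.1, 0.1))
      contam <- lw[runif(n_lw) < contamination]
      if (length(contam) > 0) {
        pick_cause <- runif(length(contam)) < 0.5
        out$cause[contam[pick_cause]] <-
          sample(codes$excluded_causes, sum(pick_cause), replace = TRUE)
        out$source_type[contam[!pick_cause]] <-
          sample(codes$excluded_types, sum(!pick_cause), replace = TRUE)
      }
      materials <- c("crude oil", "diesel", "unspecified oil sheen",
                     "produced water", "caustic solution")
      out$description[lw] <- sprintf(
        "release of %s near facility grounds",
        sample(materials, n_lw, replace = TRUE))
      kw <- lw[runif(n_lw) < air_keyword_frac]
      if (length(kw) > 0) {
        out$description[kw] <- paste(
          out$description[kw],
          sample(c("unit resumed flaring", "scrubber offline",
                   "vented to atmosphere"), length(kw), replace = TRUE))
      }
      out$is_update[lw] <- runif(n_lw) < update_frac
      out$x[lw] <- out$x[lw] + rnorm(n_lw, 0, 1)
      out$y[lw] <- out$y[lw] + rnorm(n_lw, 0, 1)
      drop_geo <- lw[runif(n_lw) < ungeocoded_frac]
      out$x[drop_geo] <- NA_real_
      out$y[drop_geo] <- NA_real_
      # land/water reports are not tied to a regulated facility downstream
    }
    out
    }
  })
  out
}

empty_reports <- function() {
  out <- tibble(
    report_id = character(), medium = character(),
    facility_id = character(), x = numeric(), y = numeric(),
    date = as.Date(character()), cause = character(),
    source_type = character(), description = character(),
    is_update = logical()
  )
  for (k in names(pollutant_group_keys())) out[[paste0("lbs_", k)]] <- numeric()
  out
}

#' Generate a synthetic gridded wind field
#'
#' Hourly zonal (`u`, eastward positive) and meridional (`v`, northward
#' positive) wind components, m/s, on a square grid of points covering the
#' region at `grid_step_km` spacing. Three regimes are available:
#' `"constant"` fixes `(u, v) = (u0, v0)` at every point-hour (the oracle
#' regime for exposure tests), `"rotating"` sweeps the direction through 360
#' degrees over each day, and `"random"` draws a smooth random direction per
#' point-day with hourly jitter, occasional calm hours, and log-normal speeds.
#'
#' @param region Block-group tibble from [generate_region()].
#' @param dates Vector of Dates (non-empty).
#' @param grid_step_km Grid spacing, km (> 0).
#' @param regime `"constant"`, `"rotating"`, or `"random"`.
#' @param seed Integer seed (random regime).
#' @param u0,v0 Components for the constant regime.
#' @param calm_frac Probability of a calm hour (random regime).
#' @return Tibble: `point_id`, `x`, `y`, `date`, `hour` (0-23), `u`, `v`.
#' @export
generate_wind <- function(region, dates, grid_step_km = 10,
                          regime = c("constant", "rotating", "random"),
                          seed = 1, u0 = 1, v0 = 0, calm_frac = 0.01) {
  regime <- match.arg(regime)
  check_number(grid_step_km, "grid_step_km", min = 0, strict_min = TRUE)
  if (length(dates) == 0) abort("`dates` must contain at least one date.")
  dates <- as.Date(dates)

  cell <- attr(region, "cell_km") %||% 1
  xmax <- max(region$col) * cell
  ymax <- max(region$row) * cell
  gx <- seq(grid_step_km / 2, max(xmax, grid_step_km / 2), by = grid_step_km)
  gy <- seq(grid_step_km / 2, max(ymax, grid_step_km / 2), by = grid_step_km)
  pts <- tidyr::expand_grid(x = gx, y = gy)
  pts$point_id <- sprintf("wp%04d", seq_len(nrow(pts)))

  frame <- tidyr::expand_grid(pts, date = dates, hour = 0:23)
  n <- nrow(frame)

  if (regime == "constant") {
    frame$u <- rep(u0, n)
    frame$v <- rep(v0, n)
  } else if (regime == "rotating") {
    ang <- 2 * pi * frame$hour / 24
    frame$u <- 3 * cos(ang)
    frame$v <- 3 * sin(ang)
  } else {
    frame <- with_seed(derive_seed(seed, 4), {
      key <- paste(frame$point_id, frame$date)
      base <- runif(length(unique(key)), 0, 360)
      names(base) <- unique(key)
      dir <- (base[key] + cumsum_jitter(n)) %% 360
      speed <- rlnorm(n, log(3), 0.4)
      calm <- runif(n) < calm_frac
      frame$u <- ifelse(calm, 0, speed * cos(dir * pi / 180))
      frame$v <- ifelse(calm, 0, speed * sin(dir * pi / 180))
      frame
    })
  }
  frame[, c("point_id", "x", "y", "date", "hour", "u", "v")]
}

cumsum_jitter <- function(n) rnorm(n, 0, 8)

#' Simulation truth for model-based synthetic outcomes
#'
#' Bundles the generative parameters of the binary-outcome spatial model:
#' log-odds coefficients `beta` (per percentage point; per 100 persons/km^2
#' for density), Leroux mixing parameter `rho` in `[0, 1]`, spatial variance
#' `tau2 >= 0`, and the `intercept` log-odds.
#'
#' @param beta Named numeric vector of log-odds coefficients.
#' @param rho Leroux mixing parameter in `[0, 1]`.
#' @param tau2 Spatial variance (>= 0).
#' @param intercept Intercept log-odds.
#' @return Object of class `sim_truth`.
#' @export
sim_truth <- function(beta, rho = 0.8, tau2 = 0.5, intercept = 0) {
  if (!is.numeric(beta)) abort("`beta` must be numeric.")
  check_number(rho, "rho", min = 0, max = 1)
  check_number(tau2, "tau2", min = 0)
  check_number(intercept, "intercept")
  structure(list(beta = beta, rho = rho, tau2 = tau2, intercept = intercept),
            class = "sim_truth")
}

#' Draw Leroux CAR spatial random effects
#'
#' Samples `phi ~ N(0, tau2 * Q(rho)^-1)` with precision
#' `Q(rho) = rho (D - W) + (1 - rho) I`, where `W` is the 0/1 adjacency
#' matrix and `D` the diagonal of its row sums — the Gaussian prior used by
#' the Leroux CAR model. At `rho = 1` on a disconnected (or any) graph the
#' precision is singular and an error asks for `rho < 1`.
#'
#' @param W Symmetric 0/1 adjacency matrix (base or `Matrix` sparse), zero
#'   diagonal.
#' @param rho Mixing parameter in `[0, 1]`.
#' @param tau2 Spatial variance (>= 0).
#' @param seed Integer seed.
#' @return Numeric vector of spatial effects.
#' @export
sample_leroux_effects <- function(W, rho, tau2, seed) {
  W <- as_adjacency_matrix(W)
  n <- nrow(W)
  check_number(rho, "rho", min = 0, max = 1)
  check_number(tau2, "tau2", min = 0)
  if (tau2 == 0) return(rep(0, n))
  D <- Matrix::Diagonal(x = Matrix::rowSums(W))
  Q <- rho * (D - W) + (1 - rho) * Matrix::Diagonal(n)
  R <- tryCatch(Matrix::chol(Q), error = function(e) NULL)
  if (is.null(R)) {
    abort(paste0("the Leroux precision matrix is singular (rho = ", rho,
                 " on a graph with disconnected components); ",
                 "use rho < 1 or connect the graph."))
  }
  z <- with_seed(derive_seed(seed, 5), rnorm(n))
  as.numeric(Matrix::solve(R, z)) * sqrt(tau2)
}

#' Generate binary outcomes from the spatial logistic model
#'
#' The generative twin of the fitted disparity model: draws spatial effects
#' `phi` from the Leroux CAR Gaussian (see [sample_leroux_effects()]) and
#' then `y_i ~ Bernoulli(plogis(intercept + x_i' beta + phi_i))`.
#'
#' @param X Numeric matrix or data frame of covariates (no intercept
#'   column); columns must align with `truth$beta`.
#' @param W Adjacency matrix, rows aligned with `X`.
#' @param truth A [sim_truth()] object.
#' @param seed Integer seed.
#' @return Tibble with `y` (0/1), `phi`, `eta` (linear predictor), `p`.
#' @export
generate_outcomes <- function(X, W, truth, seed) {
  if (!inherits(truth, "sim_truth")) abort("`truth` must be a sim_truth object.")
  X <- as.matrix(X)
  W <- as_adjacency_matrix(W)
  if (nrow(X) != nrow(W)) {
    abort("`X` must have one row per block group in `W`.")
  }
  if (ncol(X) != length(truth$beta)) {
    abort("`truth$beta` must have one coefficient per column of `X`.")
  }
  phi <- sample_leroux_effects(W, truth$rho, truth$tau2, seed)
  eta <- truth$intercept + as.numeric(X %*% truth$beta) + phi
  p <- plogis(eta)
  y <- with_seed(derive_seed(seed, 6), rbinom(length(p), 1, p))
  tibble(y = y, phi = phi, eta = eta, p = p)
}

# Accept a queen_adjacency object, a Matrix sparse matrix, or a base matrix;
# validate symmetry and zero diagonal.
as_adjacency_matrix <- function(W) {
  if (inherits(W, "queen_adjacency")) W <- W$W
  W <- methods::as(methods::as(Matrix::Matrix(W, sparse = TRUE),
                               "generalMatrix"), "CsparseMatrix")
  if (nrow(W) != ncol(W)) abort("`W` must be square.")
  if (!Matrix::isSymmetric(W)) abort("`W` must be symmetric.")
  if (any(Matrix::diag(W) != 0)) abort("`W` must have a zero diagonal.")
  W
}
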