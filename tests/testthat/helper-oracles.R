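# Independent brute-force oracles and fixture builders. Everything here is
# deliberately written from scratch (plain loops, no calls into the package's
# classification or summary code) so it can serve as an independent check.

# ---- geometry, re-derived ---------------------------------------------------

oracle_seg_dist <- function(px, py, ax, ay, bx, by) {
  vx <- bx - ax; vy <- by - ay
  L2 <- vx * vx + vy * vy
  t <- if (L2 == 0) 0 else ((px - ax) * vx + (py - ay) * vy) / L2
  t <- max(0, min(1, t))
  sqrt((px - (ax + t * vx))^2 + (py - (ay + t * vy))^2)
}

oracle_point_in_poly <- function(px, py, ring) {
  if (ring[1, 1] != ring[nrow(ring), 1] || ring[1, 2] != ring[nrow(ring), 2]) {
    ring <- rbind(ring, ring[1, ])
  }
  n <- nrow(ring) - 1
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    yi <- ring[i, 2]; yj <- ring[j, 2]
    if ((yi > py) != (yj > py)) {
      xint <- ring[i, 1] + (py - yi) / (yj - yi) * (ring[j, 1] - ring[i, 1])
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

oracle_poly_dist <- function(px, py, ring) {
  if (ring[1, 1] != ring[nrow(ring), 1] || ring[1, 2] != ring[nrow(ring), 2]) {
    ring <- rbind(ring, ring[1, ])
  }
  if (oracle_point_in_poly(px, py, ring)) return(0)
  d <- Inf
  for (i in seq_len(nrow(ring) - 1)) {
    d <- min(d, oracle_seg_dist(px, py, ring[i, 1], ring[i, 2],
                                ring[i + 1, 1], ring[i + 1, 2]))
  }
  d
}

oracle_circ_diff <- function(a, b) {
  d <- abs(a - b) %% 360
  min(d, 360 - d)
}

# ---- brute-force air-exposure classifier ------------------------------------
# Enumerates every (block group, facility, day) triple and applies the
# classification rules literally, with precedence
# exposed > upwind-excluded > at-risk > unexposed > far-excluded.
oracle_classify_air <- function(block_groups, facilities, events, dominant,
                                r_near = 2, r_far = 10, use_wind = TRUE,
                                half_width = 45) {
  n_bg <- nrow(block_groups)
  labels <- character(n_bg)
  ev_days <- unique(events[, c("facility_id", "date")])
  event_facs <- unique(events$facility_id)
  for (i in seq_len(n_bg)) {
    ring <- block_groups$geometry[[i]]
    cx <- block_groups$cx[i]; cy <- block_groups$cy[i]
    d_fac <- vapply(seq_len(nrow(facilities)), function(j) {
      oracle_poly_dist(facilities$x[j], facilities$y[j], ring)
    }, numeric(1))
    near_any <- any(d_fac < r_near)
    near_event <- FALSE
    downwind_once <- FALSE
    for (k in seq_len(nrow(ev_days))) {
      j <- which(facilities$facility_id == ev_days$facility_id[k])
      if (d_fac[j] >= r_near) next
      near_event <- TRUE
      if (!use_wind) {
        downwind_once <- TRUE
        next
      }
      day <- dominant[dominant$date == ev_days$date[k], ]
      dd <- sqrt((day$x - facilities$x[j])^2 + (day$y - facilities$y[j])^2)
      day <- day[order(dd, day$point_id), ]
      if (day$calm[1]) next
      bearing <- (atan2(cy - facilities$y[j], cx - facilities$x[j]) * 180 / pi) %% 360
      if (oracle_circ_diff(day$direction_deg[1], bearing) <= half_width) {
        downwind_once <- TRUE
      }
    }
    labels[i] <-
      if (near_event && downwind_once) "exposed"
      else if (use_wind && near_event) "excluded"
      else if (near_any) "at_risk"
      else if (min(d_fac) <= r_far) "unexposed"
      else "excluded"
  }
  labels
}

# random layout shared by the oracle-equivalence tests
random_air_layout <- function(seed) {
  set.seed(seed)
  nr <- sample(5:14, 1); nc <- sample(5:14, 1)
  region <- generate_region(region_spec(nr, nc, 1, seed = seed))
  n_fac <- sample(2:20, 1)
  fac <- tibble::tibble(
    facility_id = sprintf("f%02d", seq_len(n_fac)),
    x = runif(n_fac, 0, nc), y = runif(n_fac, 0, nr)
  )
  n_days <- sample(1:5, 1)
  dates <- as.Date("2017-08-23") + seq_len(n_days) - 1
  n_ev <- sample(1:8, 1)
  events <- tibble::tibble(
    facility_id = sample(fac$facility_id, n_ev, replace = TRUE),
    date = sample(dates, n_ev, replace = TRUE)
  )
  n_pts <- sample(1:4, 1)
  pts <- tibble::tibble(point_id = sprintf("wp%02d", seq_len(n_pts)),
                        x = runif(n_pts, 0, nc), y = runif(n_pts, 0, nr))
  dominant <- tidyr::expand_grid(pts, date = dates)
  dominant$direction_deg <- runif(nrow(dominant), 0, 360)
  dominant$calm <- runif(nrow(dominant)) < 0.15
  dominant$direction_deg[dominant$calm] <- NA_real_
  list(region = region, facilities = fac, events = events, dominant = dominant)
}

# ---- printed-table fixture --------------------------------------------------
# Builds an event/facility table whose per-category event counts and mass
# subtotals equal a supplied panel, with each facility reporting at least one
# event and the requested number of distinct reporting facilities.
table1_fixture <- function(panel, n_facilities, period = "hurricane") {
  stopifnot(sum(panel$n_fac) == n_facilities, all(panel$n_events >= panel$n_fac))
  events <- list()
  facs <- list()
  fid <- 0
  for (r in seq_len(nrow(panel))) {
    n_ev <- panel$n_events[r]
    total <- panel$total_lbs[r]
    masses <- if (n_ev == 1) total else c(rep(1, n_ev - 1), total - (n_ev - 1))
    ids <- sprintf("fx%03d", fid + seq_len(panel$n_fac[r]))
    fid <- fid + panel$n_fac[r]
    facs[[r]] <- tibble::tibble(facility_id = ids, category = panel$category[r])
    events[[r]] <- tibble::tibble(
      report_id = paste0(panel$category[r], "_", seq_len(n_ev)),
      medium = "air",
      facility_id = rep(ids, length.out = n_ev),
      date = as.Date("2017-08-23"),
      cause = "other",
      period_label = period,
      lbs_co = masses
    )
  }
  list(events = dplyr::bind_rows(events), facilities = dplyr::bind_rows(facs))
}

# Table-style panels: per-category event counts, mass subtotals, and a chosen
# facility allocation consistent with the distinct-facility total.
rita_panel <- function() {
  tibble::tribble(
    ~category, ~n_events, ~total_lbs, ~n_fac,
    "petroleum refineries", 14L, 2364350, 8L,
    "petrochemical manufacturing", 87L, 2195730, 24L,
    "plastics, resin, and other manufacturing", 8L, 15093, 6L,
    "fossil fuel extraction, transmission, and power generation", 5L, 14274, 3L,
    "warehousing, storage, and other", 1L, 187, 1L
  )
}
ike_panel <- function() {
  tibble::tribble(
    ~category, ~n_events, ~total_lbs, ~n_fac,
    "petroleum refineries", 20L, 1841154, 12L,
    "petrochemical manufacturing", 50L, 1208417, 28L,
    "plastics, resin, and other manufacturing", 17L, 21576, 8L,
    "fossil fuel extraction, transmission, and power generation", 6L, 18293, 3L
  )
}
harvey_panel <- function() {
  tibble::tribble(
    ~category, ~n_events, ~total_lbs, ~n_fac,
    "petroleum refineries", 31L, 5404634, 15L,
    "petrochemical manufacturing", 45L, 1619514, 22L,
    "plastics, resin, and other manufacturing", 7L, 102267, 5L,
    "fossil fuel extraction, transmission, and power generation", 8L, 383995, 4L,
    "warehousing, storage, and other", 3L, 2638461, 2L
  )
}

# type-7 sample quantile written out from the order-statistics definition
oracle_quantile7 <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  if (lo >= n) return(x[n])
  x[lo] + (h - lo) * (x[lo + 1] - x[lo])
}

# minimal hand-built car_fit for summary-extraction tests
fake_car_fit <- function(beta_draws_per_chain, terms = colnames(beta_draws_per_chain[[1]])) {
  n_iter <- nrow(beta_draws_per_chain[[1]])
  structure(list(
    chains = lapply(beta_draws_per_chain, function(b) list(beta = b)),
    terms = terms, n = NA_integer_,
    n_chains = length(beta_draws_per_chain),
    n_iter = n_iter, burn_in = 0, conf_level = 0.95
  ), class = "car_fit")
}
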