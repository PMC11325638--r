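#' Specify a synthetic study region
#'
#' A synthetic region is a contiguous `n_rows` by `n_cols` grid of square
#' block groups of side `cell_km`, partitioned into `n_counties` contiguous
#' counties. Coordinates are planar kilometres (no geographic CRS): exact
#' geometry keeps the spatial tests fast and free of projection error.
#'
#' @param n_rows,n_cols Grid dimensions (positive integers).
#' @param cell_km Side length of each square block group, km (> 0).
#' @param n_counties Number of counties; must satisfy
#'   `1 <= n_counties <= n_rows * n_cols`.
#' @param seed Integer seed controlling every random draw downstream.
#' @return An object of class `region_spec`.
#' @export
#' @examples
#' region_spec(4, 4, 1, n_counties = 2, seed = 1)
region_spec <- function(n_rows, n_cols, cell_km = 1, n_counties = 1, seed = 1) {
  check_number(n_rows, "n_rows", min = 1, integerish = TRUE)
  check_number(n_cols, "n_cols", min = 1, integerish = TRUE)
  check_number(cell_km, "cell_km", min = 0, strict_min = TRUE)
  check_number(n_counties, "n_counties", min = 1, integerish = TRUE)
  check_number(seed, "seed", integerish = TRUE)
  if (n_counties > n_rows * n_cols) {
    abort("`n_counties` must not exceed n_rows * n_cols.")
  }
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         cell_km = as.numeric(cell_km), n_counties = as.integer(n_counties),
         seed = as.integer(seed)),
    class = "region_spec"
  )
}

#' @method print region_spec
#' @export
print.region_spec <- function(x, ...) {
  cat(sprintf("<region_spec> %d x %d grid, cell %g km, %d counties, seed %d\n",
              x$n_rows, x$n_cols, x$cell_km, x$n_counties, x$seed))
  invisible(x)
}

#' Generate a synthetic block-group region with correlated demographics
#'
#' Builds the grid of square block-group polygons described by a
#' [region_spec()] and attaches a correlated demographic profile to each.
#' Race/ethnicity percentages come from a spatial Dirichlet model: gamma
#' shape parameters vary with a smooth "urban core" gradient so that the
#' non-White share and population density rise towards a randomly placed
#' core, mimicking the urban concentration of communities of color near
#' industrial corridors. Percentages always sum to 100 exactly (closure is by
#' construction, not rounding).
#'
#' @param spec A [region_spec()].
#' @return A tibble with one row per block group: identifiers, grid position,
#'   county, centroid (`cx`, `cy`, km), `area_km2`, a `geometry` list-column
#'   of closed polygon rings, race/ethnicity percentages (`pct_hispanic`,
#'   `pct_black`, `pct_asian_pi`, `pct_other`, `pct_white`), social
#'   vulnerability percentages (`pct_poverty`, `pct_renters`,
#'   `pct_no_vehicle`), and `pop_density` (hundreds of persons per km^2).
#'   The `cell_km` value is kept as an attribute.
#' @export
#' @examples
#' region <- generate_region(region_spec(4, 4, 1, n_counties = 2, seed = 42))
#' dplyr::glimpse(region[1:3, ])
generate_region <- function(spec) {
  if (!inherits(spec, "region_spec")) {
    abort("`spec` must be a `region_spec` object (see region_spec()).")
  }
  n <- spec$n_rows * spec$n_cols
  row <- rep(seq_len(spec$n_rows), each = spec$n_cols)
  col <- rep(seq_len(spec$n_cols), times = spec$n_rows)
  s <- spec$cell_km

  geometry <- purrr::map2(col, row, function(cc, rr) {
    x0 <- (cc - 1) * s; y0 <- (rr - 1) * s
    m <- rbind(c(x0, y0), c(x0 + s, y0), c(x0 + s, y0 + s),
               c(x0, y0 + s), c(x0, y0))
    colnames(m) <- c("x", "y")
    m
  })
  cx <- (col - 0.5) * s
  cy <- (row - 0.5) * s

  # Counties: contiguous blocks of consecutive row-major cells.
  cell_index <- seq_len(n)
  county <- ceiling(cell_index * spec$n_counties / n)

  demo <- with_seed(derive_seed(spec$seed, 1), {
    core_x <- runif(1, 0, spec$n_cols * s)
    core_y <- runif(1, 0, spec$n_rows * s)
    scale <- 0.4 * max(spec$n_cols, spec$n_rows) * s
    d <- sqrt((cx - core_x)^2 + (cy - core_y)^2)
    g <- exp(-d / max(scale, 1e-9)) # 1 at the core, ~0 at the fringe

    # Dirichlet via independent gammas; shapes shift with the core gradient
    # so pct_white is anticorrelated with the other groups.
    sh_white <- 8 * (1 - 0.6 * g)
    sh_hisp  <- 4 * (1 + 0.9 * g)
    sh_black <- 2.5 * (1 + 0.6 * g)
    sh_asian <- 0.8 * (1 + 0.4 * g)
    sh_other <- 0.35
    gw <- rgamma(n, sh_white); gh <- rgamma(n, sh_hisp)
    gb <- rgamma(n, sh_black); ga <- rgamma(n, sh_asian)
    go <- rgamma(n, sh_other)
    tot <- gw + gh + gb + ga + go

    tibble(
      pct_hispanic = 100 * gh / tot,
      pct_black    = 100 * gb / tot,
      pct_asian_pi = 100 * ga / tot,
      pct_other    = 100 * go / tot,
      pct_white    = 100 * gw / tot,
      pct_poverty    = 100 * rbeta(n, 1.5 + 2 * g, 4.5 - 2 * g),
      pct_renters    = 100 * rbeta(n, 1.5 + 1.5 * g, 3.5),
      pct_no_vehicle = 100 * rbeta(n, 1 + g, 9),
      pop_density    = rlnorm(n, meanlog = log(3) + 2 * g, sdlog = 0.6)
    )
  })

  out <- dplyr::bind_cols(
    tibble(
      block_group_id = sprintf("bg%05d", cell_index),
      row = row, col = col,
      county_id = sprintf("county%03d", county),
      cx = cx, cy = cy,
      area_km2 = s^2,
      geometry = geometry
    ),
    demo
  )
  attr(out, "cell_km") <- s
  attr(out, "crs") <- "planar_km"
  out
}

#' Facility NAICS categories used throughout the package
#'
#' The five regulated-facility groupings used when classifying point sources.
#'
#' @return Character vector of category names.
#' @export
naics_categories <- function() {
  c("petrochemical manufacturing",
    "petroleum refineries",
    "plastics, resin, and other manufacturing",
    "fossil fuel extraction, transmission, and power generation",
    "warehousing, storage, and other")
}

#' Generate synthetic regulated facilities
#'
#' Places point-source facilities uniformly at random within the region
#' bounds. Each facility carries a NAICS category and the set of years in
#' which it reported to the emissions inventory (a random subset of
#' `years`, each year kept with probability `1 - dropout`).
#'
#' @param region A block-group tibble from [generate_region()].
#' @param n_per_category Named integer vector or list: facilities per
#'   category. Names must be among [naics_categories()].
#' @param seed Integer seed.
#' @param years Candidate reporting years.
#' @param dropout Per-year probability that a facility skipped reporting.
#' @return Tibble with `facility_id`, `category`, `x`, `y`, `county_id`, and a
#'   `reporting_years` list-column.
#' @export
#' @examples
#' region <- generate_region(region_spec(5, 5, 1, seed = 1))
#' generate_facilities(region, c("petroleum refineries" = 2), seed = 9)
generate_facilities <- function(region, n_per_category, seed,
                                years = c(2005:2009, 2016:2018),
                                dropout = 0.15) {
  check_columns(region, c("cx", "cy", "geometry", "county_id"), "region")
  if (nrow(region) == 0) abort("`region` must contain at least one block group.")
  n_per_category <- unlist(n_per_category)
  bad <- setdiff(names(n_per_category), naics_categories())
  if (length(bad) > 0 || is.null(names(n_per_category))) {
    abort(sprintf(
      "unknown facility category: %s. Valid categories are: %s.",
      paste(bad, collapse = ", "),
      paste(naics_categories(), collapse = "; ")
    ))
  }
  if (any(n_per_category < 0)) abort("facility counts must be >= 0.")
  n_total <- sum(n_per_category)
  category <- rep(names(n_per_category), times = n_per_category)

  cell <- attr(region, "cell_km") %||% 1
  xmax <- max(region$col) * cell
  ymax <- max(region$row) * cell

  with_seed(derive_seed(seed, 2), {
    x <- runif(n_total, 0, xmax)
    y <- runif(n_total, 0, ymax)
    reporting_years <- purrr::map(seq_len(n_total), function(i) {
      keep <- runif(length(years)) > dropout
      if (!any(keep)) keep[sample.int(length(years), 1)] <- TRUE
      years[keep]
    })
    # County of the containing cell (facilities are points, cells tile space).
    ccol <- pmin(pmax(ceiling(x / cell), 1), max(region$col))
    crow <- pmin(pmax(ceiling(y / cell), 1), max(region$row))
    idx <- (crow - 1) * max(region$col) + ccol
    tibble(
      facility_id = sprintf("fac%04d", seq_len(n_total)),
      category = category,
      x = x, y = y,
      county_id = region$county_id[idx],
      reporting_years = reporting_years
    )
  })
}
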