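#' Pipeline configuration
#'
#' Assembles and validates the configuration for [run_pipeline()]. Defaults
#' reproduce the packaged demo: a synthetic region, one hurricane window
#' with two matched reference windows, buffer radii of 2 and 10 km, a
#' 45-degree downwind sector half-width, and the county-screening thresholds
#' (141 mm rain, 64 knots, 24 facilities). Unknown keys are rejected so
#' typos fail fast, and every threshold must be positive before any stage
#' runs.
#'
#' @param ... Named overrides of the defaults (see
#'   `pipeline_config_defaults()`); nested lists (`region`, `facilities`,
#'   `reports`, `wind`, `thresholds`, `mcmc`) are merged key by key.
#' @param seed Master seed for every stage.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(..., seed = 1) {
  defaults <- pipeline_config_defaults()
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0) {
    abort(sprintf("unknown configuration key(s): %s.",
                  paste(unknown, collapse = ", ")))
  }
  cfg <- defaults
  for (key in names(overrides)) {
    if (is.list(defaults[[key]]) && is.list(overrides[[key]])) {
      inner_unknown <- setdiff(names(overrides[[key]]), names(defaults[[key]]))
      if (length(inner_unknown) > 0) {
        abort(sprintf("unknown configuration key(s) in `%s`: %s.", key,
                      paste(inner_unknown, collapse = ", ")))
      }
      cfg[[key]][names(overrides[[key]])] <- overrides[[key]]
    } else {
      cfg[[key]] <- overrides[[key]]
    }
  }
  cfg$seed <- as.integer(seed)
  validate_pipeline_config(cfg)
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @export
pipeline_config_defaults <- function() {
  list(
    region = list(n_rows = 20, n_cols = 20, cell_km = 1, n_counties = 3),
    facilities = list(
      "petrochemical manufacturing" = 6,
      "petroleum refineries" = 3,
      "plastics, resin, and other manufacturing" = 3,
      "fossil fuel extraction, transmission, and power generation" = 2,
      "warehousing, storage, and other" = 2
    ),
    reports = list(rate_hurricane = 0.06, rate_reference = 0.02,
                   p_air = 0.5, contamination = 0.2),
    hurricane = list(label = "hurricane", start = "2017-08-23",
                     end = "2017-09-05"),
    reference_years = c(2016, 2018),
    wind = list(regime = "random", grid_step_km = 6),
    thresholds = list(r_near = 2, r_far = 10, half_width = 45,
                      rain_mm = 141, wind_knots = 64, facilities = 24),
    mcmc = list(chains = 3, n_iter = 6000, burn_in = 3000,
                beta_prior_var = 1e5),
    seed = 1L
  )
}

validate_pipeline_config <- function(cfg) {
  th <- cfg$thresholds
  for (nm in names(th)) {
    check_number(th[[nm]], paste0("thresholds$", nm), min = 0,
                 strict_min = TRUE)
  }
  if (th$r_near >= th$r_far) abort("thresholds$r_near must be < thresholds$r_far.")
  sp <- study_period(cfg$hurricane$label, cfg$hurricane$start,
                     cfg$hurricane$end)
  if (any(cfg$reference_years == sp$year)) {
    abort("reference_years must differ from the hurricane year.")
  }
  for (nm in c("rate_hurricane", "rate_reference")) {
    check_number(cfg$reports[[nm]], paste0("reports$", nm), min = 0)
  }
  check_number(cfg$mcmc$chains, "mcmc$chains", min = 1, integerish = TRUE)
  check_number(cfg$mcmc$n_iter, "mcmc$n_iter", min = 2, integerish = TRUE)
  check_number(cfg$mcmc$burn_in, "mcmc$burn_in", min = 0, integerish = TRUE)
  if (cfg$mcmc$burn_in >= cfg$mcmc$n_iter) {
    abort("mcmc$burn_in must be smaller than mcmc$n_iter.")
  }
  check_number(cfg$mcmc$beta_prior_var, "mcmc$beta_prior_var", min = 0,
               strict_min = TRUE)
  invisible(cfg)
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file of configuration overrides.
#' @param seed Optional seed override (e.g. from the command line).
#' @return A validated [pipeline_config()].
#' @export
read_pipeline_config <- function(path, seed = NULL) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s.", path))
  raw <- yaml::read_yaml(path)
  seed <- seed %||% raw$seed %||% 1
  raw$seed <- NULL
  do.call(pipeline_config, c(raw, list(seed = seed)))
}

#' Run the full synthetic pipeline
#'
#' Executes simulate, screen, classify, summarize, and fit in order, writing
#' each stage's outputs plus a manifest to `out_dir`. A stage failure halts
#' the pipeline with the stage name and cause. The manifest records the
#' seed, the configuration, the package version, and an MD5 hash of every
#' written file, so identical configuration and seed yield identical
#' manifests.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the stage outputs (`region`,
#'   `facilities`, `reports`, `exposure`, summaries, `analysis`) and the
#'   manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  if (!inherits(config, "pipeline_config")) {
    abort("`config` must be a pipeline_config object.")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(writer, obj, name) {
    p <- file.path(out_dir, name)
    writer(obj, p)
    written <<- c(written, p)
    p
  }
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }
  seed <- config$seed

  # --- simulate -------------------------------------------------------------
  sim <- stage("simulate", {
    region <- generate_region(region_spec(
      config$region$n_rows, config$region$n_cols, config$region$cell_km,
      config$region$n_counties, seed = seed))
    facilities <- generate_facilities(region, unlist(config$facilities),
                                      seed = seed)
    hurricane <- study_period(config$hurricane$label, config$hurricane$start,
                              config$hurricane$end)
    references <- dplyr::bind_rows(lapply(config$reference_years, function(yy) {
      build_reference_period(hurricane, yy)
    }))
    periods <- dplyr::bind_rows(hurricane, references)
    reports <- generate_reports(
      facilities, periods,
      rate_hurricane = config$reports$rate_hurricane,
      rate_reference = config$reports$rate_reference,
      seed = seed, p_air = config$reports$p_air,
      contamination = config$reports$contamination)
    all_dates <- sort(unique(unlist(lapply(seq_len(nrow(periods)), function(i) {
      as.character(seq(periods$start[i], periods$end[i], by = "day"))
    }))))
    wind <- generate_wind(region, as.Date(all_dates),
                          grid_step_km = config$wind$grid_step_km,
                          regime = config$wind$regime, seed = seed)
    emit(write_blockgroups, region, "blockgroups.geojson")
    emit(write_facilities, facilities, "facilities.csv")
    emit(write_reports, reports[reports$medium == "air", ], "reports_air.csv")
    emit(write_reports, reports[reports$medium == "land_water", ],
         "reports_landwater.csv")
    emit(write_wind, wind, "wind.csv")
    list(region = region, facilities = facilities, reports = reports,
         periods = periods, wind = wind, hurricane = hurricane)
  })

  # --- screen ---------------------------------------------------------------
  screened <- stage("screen", {
    lw <- sim$reports[sim$reports$medium == "land_water", , drop = FALSE]
    retained <- filter_landwater(lw)
    exclusions <- exclusion_log(retained)
    air <- assign_period(sim$reports[sim$reports$medium == "air", ,
                                     drop = FALSE], sim$periods)
    retained <- assign_period(retained, sim$periods)
    emit(write_reports, retained, "reports_landwater_retained.csv")
    emit(function(obj, p) readr::write_csv(obj, p), exclusions,
         "exclusions_landwater.csv")
    list(air = air, landwater = retained, exclusions = exclusions)
  })

  # --- classify -------------------------------------------------------------
  exposure <- stage("classify", {
    th <- config$thresholds
    dominant <- daily_dominant(sim$wind)
    air_events <- screened$air[
      !is.na(screened$air$period_label) &
        screened$air$period_label == "hurricane", , drop = FALSE]
    lw_hur <- screened$landwater[
      !is.na(screened$landwater$period_label) &
        screened$landwater$period_label == "hurricane", , drop = FALSE]
    air_cls <- classify_air(sim$region, sim$facilities, air_events, dominant,
                            r_near = th$r_near, r_far = th$r_far,
                            half_width = th$half_width)
    lw_cls <- classify_landwater(sim$region, lw_hur,
                                 r_near = th$r_near, r_far = th$r_far)
    exposure <- dplyr::left_join(air_cls, lw_cls, by = "block_group_id")
    emit(function(obj, p) readr::write_csv(obj, p), exposure, "exposure.csv")
    exposure
  })

  # --- summarize ------------------------------------------------------------
  summaries <- stage("summarize", {
    air_sum <- summarize_air(screened$air, sim$facilities)
    lw_sum <- summarize_landwater(screened$landwater)
    ratios <- dplyr::bind_rows(period_ratio(air_sum), period_ratio(lw_sum))
    emit(function(obj, p) readr::write_csv(obj, p), air_sum$overall,
         "summary_air_overall.csv")
    emit(function(obj, p) readr::write_csv(obj, p), air_sum$by_facility_type,
         "summary_air_by_facility_type.csv")
    emit(function(obj, p) readr::write_csv(obj, p), air_sum$by_pollutant,
         "summary_air_by_pollutant.csv")
    emit(function(obj, p) readr::write_csv(obj, p), lw_sum$by_source_type,
         "summary_landwater_by_source_type.csv")
    emit(function(obj, p) readr::write_csv(obj, p), ratios, "period_ratios.csv")
    list(air = air_sum, landwater = lw_sum, ratios = ratios)
  })

  # --- fit ------------------------------------------------------------------
  analysis <- stage("fit", {
    analysis <- run_disparity_analysis(
      sim$region, exposure,
      chains = config$mcmc$chains, n_iter = config$mcmc$n_iter,
      burn_in = config$mcmc$burn_in, seed = seed,
      priors = car_priors(beta_var = config$mcmc$beta_prior_var))
    emit(function(obj, p) readr::write_csv(obj, p), analysis$or_table,
         "or_table.csv")
    emit(function(obj, p) {
      jsonlite::write_json(obj, p, auto_unbox = TRUE, digits = 10)
    }, analysis$diagnostics, "diagnostics.json")
    analysis
  })

  manifest <- list(
    package = "natechdisparity",
    version = as.character(utils::packageVersion("natechdisparity")),
    seed = seed,
    config = unclass(config),
    files = as.list(setNames(unname(tools::md5sum(written)),
                             basename(written)))
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = 10, pretty = TRUE)

  invisible(list(region = sim$region, facilities = sim$facilities,
                 reports = sim$reports, periods = sim$periods,
                 screened = screened, exposure = exposure,
                 summaries = summaries, analysis = analysis,
                 manifest = manifest, out_dir = out_dir))
}
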