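#' Covariate sets for the disparity models
#'
#' Unadjusted models use the four race/ethnicity percentages (with the
#' White percentage as the omitted reference group); adjusted models add the
#' social-vulnerability indicators and population density. Units are
#' percentage points, except density (hundreds of persons per km^2), so
#' odds ratios read as "per one-percent increase".
#'
#' @param adjusted Include the social-vulnerability covariates?
#' @return Character vector of block-group column names.
#' @export
disparity_covariates <- function(adjusted = FALSE) {
  race <- c("pct_hispanic", "pct_black", "pct_asian_pi", "pct_other")
  if (adjusted) {
    c(race, "pct_no_vehicle", "pct_poverty", "pct_renters", "pop_density")
  } else {
    race
  }
}

#' Block-group disparity analysis with Leroux CAR models
#'
#' The full inferential layer for one hurricane set: for each requested
#' outcome it restricts block groups to the relevant comparison
#' (air: exposed vs at-risk; land/water: exposed vs unexposed), rebuilds
#' queen adjacency on the retained polygons (dropping and logging isolates),
#' fits the county-fixed-effect logistic baseline and tests its Pearson
#' residuals for spatial autocorrelation with Moran's I, then fits
#' unadjusted and adjusted binomial Leroux CAR models and extracts posterior
#' odds ratios.
#'
#' @param block_groups Block-group tibble (geometry + demographics).
#' @param exposure Exposure-label tibble; needs `block_group_id` plus
#'   `air_label` and/or `landwater_label` columns (join of [classify_air()]
#'   and [classify_landwater()] outputs).
#' @param outcomes Which outcomes to model.
#' @param chains,n_iter,burn_in,seed,priors MCMC settings passed to
#'   [fit_leroux_car()].
#' @param n_permutations Permutations for the Moran's I residual test.
#' @return Object of class `disparity_analysis`: `or_table` (tibble of
#'   outcome, adjusted flag, term, odds ratio, credible interval),
#'   `diagnostics` (per-model PSRF and Moran's I results), `dropped`
#'   (isolated block groups removed per outcome), and the underlying fits.
#' @export
run_disparity_analysis <- function(block_groups, exposure,
                                   outcomes = c("air", "landwater"),
                                   chains = 3, n_iter = 20000,
                                   burn_in = 10000, seed = 1,
                                   priors = car_priors(),
                                   n_permutations = 999) {
  outcomes <- match.arg(outcomes, several.ok = TRUE)
  check_columns(block_groups, c("block_group_id", "geometry", "county_id",
                                disparity_covariates(TRUE)), "block_groups")
  check_columns(exposure, "block_group_id", "exposure")
  df <- dplyr::inner_join(block_groups, exposure, by = "block_group_id")

  fits <- list()
  or_rows <- list()
  diag_rows <- list()
  dropped <- list()

  for (outcome in outcomes) {
    label_col <- if (outcome == "air") "air_label" else "landwater_label"
    check_columns(df, label_col, "exposure")
    keep_labels <- if (outcome == "air") c("exposed", "at_risk")
                   else c("exposed", "unexposed")
    rows <- df[df[[label_col]] %in% keep_labels, , drop = FALSE]
    excluded_rows <- sum(!df[[label_col]] %in% keep_labels)
    if (excluded_rows > 0) {
      inform(sprintf("%s model: %d block group(s) outside the %s comparison excluded.",
                     outcome, excluded_rows, paste(keep_labels, collapse = " vs ")))
    }
    y_all <- as.numeric(rows[[label_col]] == "exposed")
    if (length(unique(y_all)) < 2) {
      abort(sprintf("%s model: comparison group is empty (all outcomes equal).",
                    outcome))
    }

    adj <- build_queen_adjacency(rows)
    if (length(adj$dropped_ids) > 0) {
      inform(sprintf("%s model: dropped %d block group(s) with no shared boundary: %s.",
                     outcome, length(adj$dropped_ids),
                     paste(adj$dropped_ids, collapse = ", ")))
    }
    dropped[[outcome]] <- adj$dropped_ids
    rows <- rows[rows$block_group_id %in% adj$ids, , drop = FALSE]
    y <- as.numeric(rows[[label_col]] == "exposed")

    # non-spatial baseline + residual autocorrelation check
    X_adj <- as.matrix(rows[, disparity_covariates(TRUE)])
    baseline <- tryCatch(
      fit_logistic_fe(y, X_adj, rows$county_id),
      error = function(e) NULL
    )
    moran <- if (!is.null(baseline)) {
      morans_i(residuals(baseline), adj, n_permutations = n_permutations,
               seed = derive_seed(seed, 9))
    } else {
      NULL
    }

    eig <- NULL
    for (adjusted in c(FALSE, TRUE)) {
      covs <- disparity_covariates(adjusted)
      X <- as.matrix(rows[, covs])
      if (is.null(eig)) {
        M <- Matrix::Diagonal(x = Matrix::rowSums(adj$W)) - adj$W
        eig <- eigen(as.matrix(M), symmetric = TRUE, only.values = TRUE)$values
      }
      fit <- fit_leroux_car(y, X, adj, chains = chains, n_iter = n_iter,
                            burn_in = burn_in,
                            seed = derive_seed(seed, 10 + adjusted),
                            priors = priors, eigen_M = eig)
      key <- paste0(outcome, if (adjusted) "_adjusted" else "_unadjusted")
      fits[[key]] <- fit
      or_rows[[key]] <- dplyr::mutate(fit$or_summary, outcome = outcome,
                                      adjusted = adjusted, .before = 1)
      diag_rows[[key]] <- tibble(
        outcome = outcome, adjusted = adjusted,
        n = fit$n, n_exposed = sum(y),
        max_psrf = max(fit$diagnostics$psrf, na.rm = TRUE),
        moran_i = if (is.null(moran)) NA_real_ else moran$statistic,
        moran_p = if (is.null(moran)) NA_real_ else moran$p_value,
        baseline_status = if (is.null(baseline)) "failed" else baseline$status
      )
    }
    fits[[paste0(outcome, "_baseline")]] <- baseline
    fits[[paste0(outcome, "_moran")]] <- moran
  }

  structure(list(
    or_table = dplyr::bind_rows(or_rows),
    diagnostics = dplyr::bind_rows(diag_rows),
    dropped = dropped,
    fits = fits,
    settings = list(chains = chains, n_iter = n_iter, burn_in = burn_in,
                    seed = seed)
  ), class = "disparity_analysis")
}

#' @method print disparity_analysis
#' @export
print.disparity_analysis <- function(x, ...) {
  cat("Block-group disparity analysis (binomial Leroux CAR models)\n\n")
  print(x$or_table)
  cat("\nDiagnostics:\n")
  print(x$diagnostics)
  invisible(x)
}

#' @export
tidy.disparity_analysis <- function(x, ...) x$or_table

#' @export
glance.disparity_analysis <- function(x, ...) x$diagnostics

#' @export
autoplot.disparity_analysis <- function(object, ...) {
  tab <- object$or_table
  tab$model <- paste(tab$outcome, ifelse(tab$adjusted, "adjusted", "unadjusted"))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$or, y = .data$term,
                                    colour = .data$model)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high),
                             position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "odds ratio (posterior median, 95% CrI)", y = NULL,
                  colour = NULL)
}
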