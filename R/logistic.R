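#' County-fixed-effect logistic baseline
#'
#' Maximum-likelihood logistic regression of a binary exposure indicator on
#' block-group covariates with county indicator terms — the non-spatial
#' baseline whose residual autocorrelation motivates the CAR model, and the
#' oracle the CAR sampler must match in the no-spatial limit (fit with
#' `county_ids = NULL`).
#'
#' @param y Binary outcome vector (0/1); needs at least one of each.
#' @param X Covariate matrix or data frame (no intercept column).
#' @param county_ids Optional factor/character vector of county memberships;
#'   `NULL` omits the fixed effects.
#' @param conf_level Confidence level for Wald intervals.
#' @return Object of class `logistic_fe` with the glm fit, a coefficient
#'   tibble, and a `status` field: `"ok"`, `"not_converged"`, or
#'   `"separation"` (all-equal outcomes within a county, or fitted
#'   probabilities at the boundary). Non-ok fits keep their status explicit
#'   rather than failing silently.
#' @export
fit_logistic_fe <- function(y, X, county_ids = NULL, conf_level = 0.95) {
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) abort("`y` must be binary (0/1).")
  if (all(y == 1) || all(y == 0)) {
    abort("separation: `y` needs at least one event and one non-event.")
  }
  df <- as.data.frame(X)
  if (ncol(df) > 0 && is.null(colnames(X))) {
    names(df) <- paste0("x", seq_len(ncol(df)))
  }
  separation_counties <- character(0)
  if (!is.null(county_ids)) {
    tab <- tapply(y, county_ids, function(v) length(unique(v)))
    separation_counties <- names(tab)[tab == 1]
    df$county <- factor(county_ids)
  }
  df$.y <- y
  fit <- glm(.y ~ ., data = df, family = binomial())

  status <- "ok"
  if (!fit$converged) status <- "not_converged"
  eps <- 1e-8
  if (any(fit$fitted.values < eps | fit$fitted.values > 1 - eps) ||
      length(separation_counties) > 0) {
    status <- "separation"
  }
  if (status != "ok") {
    warn(sprintf("logistic baseline status: %s%s", status,
                 if (length(separation_counties) > 0) {
                   paste0(" (counties with all-equal outcomes: ",
                          paste(separation_counties, collapse = ", "), ")")
                 } else ""))
  }

  sm <- summary(fit)$coefficients
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  coefs <- tibble(
    term = rownames(sm),
    estimate = sm[, "Estimate"],
    std.error = sm[, "Std. Error"],
    statistic = sm[, "z value"],
    p.value = sm[, "Pr(>|z|)"],
    conf.low = sm[, "Estimate"] - zq * sm[, "Std. Error"],
    conf.high = sm[, "Estimate"] + zq * sm[, "Std. Error"]
  )
  structure(list(fit = fit, coefficients = coefs, status = status,
                 separation_counties = separation_counties,
                 n = length(y), conf_level = conf_level),
            class = "logistic_fe")
}

#' @method print logistic_fe
#' @export
print.logistic_fe <- function(x, ...) {
  cat(sprintf("County-fixed-effect logistic model (n = %d, status: %s)\n",
              x$n, x$status))
  print(x$coefficients[!grepl("^county", x$coefficients$term), ])
  invisible(x)
}

#' @export
tidy.logistic_fe <- function(x, exponentiate = FALSE, ...) {
  out <- x$coefficients
  if (exponentiate) {
    out$estimate <- exp(out$estimate)
    out$conf.low <- exp(out$conf.low)
    out$conf.high <- exp(out$conf.high)
  }
  out
}

#' @export
glance.logistic_fe <- function(x, ...) {
  tibble(n = x$n, status = x$status,
         converged = x$fit$converged,
         deviance = x$fit$deviance, aic = x$fit$aic,
         n_separation_counties = length(x$separation_counties))
}

#' Pearson residuals of the logistic baseline
#' @param object A `logistic_fe` fit.
#' @param ... Unused.
#' @return Numeric vector of Pearson residuals.
#' @export
residuals.logistic_fe <- function(object, ...) {
  stats::residuals(object$fit, type = "pearson")
}
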