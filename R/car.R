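#' Prior settings for the Leroux CAR model
#'
#' Defaults: independent `N(0, 10^5)` priors on the fixed effects, an
#' Inverse-Gamma(1, 0.01) prior on the spatial variance `tau2`, and a
#' Uniform(0, 1) prior on the mixing parameter `rho`.
#'
#' @param beta_var Prior variance of each fixed effect.
#' @param tau2_shape,tau2_rate Inverse-gamma shape and rate for `tau2`.
#' @return List of class `car_priors`.
#' @export
car_priors <- function(beta_var = 1e5, tau2_shape = 1, tau2_rate = 0.01) {
  check_number(beta_var, "beta_var", min = 0, strict_min = TRUE)
  check_number(tau2_shape, "tau2_shape", min = 0, strict_min = TRUE)
  check_number(tau2_rate, "tau2_rate", min = 0, strict_min = TRUE)
  structure(list(beta_var = beta_var, tau2_shape = tau2_shape,
                 tau2_rate = tau2_rate), class = "car_priors")
}

# Leroux full conditional of one spatial effect, reference implementation
# used by the tests: phi_i | phi_{-i} ~ N(rho * sum_j w_ij phi_j / d*,
# tau2 / d*) with d* = rho * sum_j w_ij + 1 - rho. At rho = 0 this is the
# independent N(0, tau2) prior.
leroux_full_conditional <- function(i, phi, W, rho, tau2) {
  W <- as_adjacency_matrix(W)
  wrow <- W[i, ]
  denom <- rho * sum(wrow) + 1 - rho
  list(mean = rho * sum(wrow * phi) / denom, var = tau2 / denom)
}

#' Fit the binomial Leroux CAR model by MCMC
#'
#' Bayesian logistic regression with a Leroux conditional autoregressive
#' spatial random effect: `y_i ~ Bernoulli(p_i)`,
#' `logit(p_i) = x_i' beta + phi_i`, with
#' `phi ~ N(0, tau2 * (rho (D - W) + (1 - rho) I)^-1)`. Chains are run
#' sequentially from overdispersed starts; proposal step sizes adapt towards
#' 40-50% acceptance during burn-in and are frozen afterwards; `phi` is
#' recentred to mean zero each sweep with the mean absorbed into the
#' intercept. The mixing-parameter update evaluates the prior
#' log-determinant through the eigenvalues of `D - W`, computed once per fit
#' (pass `eigen_M` to reuse them across fits on the same graph).
#'
#' Zero-variance covariates are dropped with a warning rather than producing
#' a singular fit. A potential scale reduction factor above 1.1 on any of
#' beta, rho, or log tau2 triggers a convergence warning.
#'
#' @param y Binary outcome (0/1), one per retained block group.
#' @param X Covariate matrix or data frame. An intercept column of ones is
#'   prepended when absent.
#' @param W A `queen_adjacency` object or symmetric 0/1 adjacency matrix
#'   aligned with `y`.
#' @param chains Number of MCMC chains.
#' @param n_iter Iterations per chain (including burn-in).
#' @param burn_in Iterations discarded per chain.
#' @param seed Integer seed; chain `c` uses a seed derived from it.
#' @param priors A [car_priors()] object.
#' @param eigen_M Optional precomputed eigenvalues of `D - W`.
#' @param phi_thin Keep every `phi_thin`-th draw of the spatial field (the
#'   full field is large; fixed-effect draws are always kept in full).
#' @param conf_level Credible-interval level for odds-ratio summaries.
#' @return Object of class `car_fit`: per-chain draws (`beta`, `rho`,
#'   `tau2`, thinned `phi`), the pooled post-burn-in odds-ratio summary,
#'   acceptance rates, and PSRF convergence diagnostics.
#' @export
#' @examples
#' \donttest{
#' region <- generate_region(region_spec(10, 10, 1, seed = 1))
#' adj <- build_queen_adjacency(region)
#' X <- cbind(pct_hispanic = region$pct_hispanic)
#' truth <- sim_truth(beta = c(pct_hispanic = log(1.05)), rho = 0.8,
#'                    tau2 = 0.5, intercept = -1.5)
#' y <- generate_outcomes(X, adj, truth, seed = 2)$y
#' fit <- fit_leroux_car(y, X, adj, chains = 2, n_iter = 1000,
#'                       burn_in = 500, seed = 3)
#' tidy(fit)
#' }
fit_leroux_car <- function(y, X, W, chains = 3, n_iter = 20000,
                           burn_in = 10000, seed = 1,
                           priors = car_priors(), eigen_M = NULL,
                           phi_thin = max(1L, n_iter %/% 200L),
                           conf_level = 0.95) {
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) abort("`y` must be binary (0/1).")
  if (!inherits(priors, "car_priors")) abort("`priors` must come from car_priors().")
  check_number(chains, "chains", min = 1, integerish = TRUE)
  check_number(n_iter, "n_iter", min = 2, integerish = TRUE)
  check_number(burn_in, "burn_in", min = 0, integerish = TRUE)
  if (burn_in >= n_iter) abort("`burn_in` must be smaller than `n_iter`.")

  W <- as_adjacency_matrix(W)
  n <- length(y)
  if (nrow(W) != n) abort("rows of `X`/`y` must align with `W`.")

  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (nrow(X) != n) abort("rows of `X`/`y` must align with `W`.")
  has_intercept <- ncol(X) > 0 && all(X[, 1] == 1)
  if (!has_intercept) {
    X <- cbind("(Intercept)" = 1, X)
  } else {
    colnames(X)[1] <- "(Intercept)"
  }
  keep <- c(TRUE, vapply(seq_len(ncol(X))[-1],
                         function(j) stats::sd(X[, j]) > 0, logical(1)))
  if (any(!keep)) {
    warn(sprintf("dropping zero-variance covariate(s): %s.",
                 paste(colnames(X)[!keep], collapse = ", ")))
    X <- X[, keep, drop = FALSE]
  }
  p <- ncol(X)

  deg <- Matrix::rowSums(W)
  if (any(deg == 0)) {
    abort("`W` contains isolated units; drop them first (see build_queen_adjacency()).")
  }
  if (is.null(eigen_M)) {
    M <- Matrix::Diagonal(x = deg) - W
    eigen_M <- eigen(as.matrix(M), symmetric = TRUE, only.values = TRUE)$values
  }
  csr <- adjacency_to_csr(W)

  # crude ML centre for overdispersed starts
  start_centre <- tryCatch(
    suppressWarnings(coef(stats::glm.fit(X, y, family = binomial()))),
    error = function(e) c(qlogis(max(min(mean(y), 1 - 1e-3), 1e-3)),
                          rep(0, p - 1))
  )
  start_centre[!is.finite(start_centre)] <- 0

  chain_out <- vector("list", chains)
  for (ch in seq_len(chains)) {
    chain_out[[ch]] <- with_seed(derive_seed(seed, 100 + ch), {
      beta0 <- start_centre + rnorm(p, 0, 0.25)
      rho0 <- runif(1, 0.1, 0.9)
      tau20 <- runif(1, 0.5, 2)
      # phi must start at the scale of tau2, otherwise the first Gibbs draw
      # of tau2 collapses and pins the spatial field at zero
      phi0 <- rnorm(n, 0, sqrt(tau20))
      car_leroux_chain(y, X, csr$adj, csr$ptr, eigen_M,
                       as.integer(n_iter), as.integer(burn_in),
                       beta0, phi0, rho0, tau20,
                       priors$beta_var, priors$tau2_shape, priors$tau2_rate,
                       as.integer(phi_thin))
    })
    colnames(chain_out[[ch]]$beta) <- colnames(X)
  }

  fit <- structure(list(
    chains = chain_out,
    terms = colnames(X),
    n = n, n_chains = chains, n_iter = n_iter, burn_in = burn_in,
    phi_thin = phi_thin, priors = priors, seed = seed,
    conf_level = conf_level
  ), class = "car_fit")
  fit$diagnostics <- car_diagnostics(fit)
  fit$or_summary <- extract_or(fit, conf_level = conf_level)
  if (any(fit$diagnostics$psrf > 1.1, na.rm = TRUE)) {
    warn(sprintf(
      "possible non-convergence: max PSRF = %.3f (parameters: %s); consider longer chains.",
      max(fit$diagnostics$psrf),
      paste(fit$diagnostics$parameter[fit$diagnostics$psrf > 1.1],
            collapse = ", ")))
  }
  fit
}

adjacency_to_csr <- function(W) {
  W <- methods::as(W, "CsparseMatrix")
  # W symmetric: columns double as rows
  list(adj = as.integer(W@i), ptr = as.integer(W@p))
}

post_burn <- function(fit, what) {
  idx <- if (fit$n_iter > fit$burn_in) {
    seq(fit$burn_in + 1L, fit$n_iter)
  } else {
    integer(0)
  }
  lapply(fit$chains, function(ch) {
    if (what == "beta") ch$beta[idx, , drop = FALSE] else ch[[what]][idx]
  })
}

#' Pooled posterior draws of the fixed effects
#' @param fit A `car_fit`.
#' @return Matrix of post-burn-in draws, chains stacked.
#' @export
pooled_beta <- function(fit) {
  do.call(rbind, post_burn(fit, "beta"))
}

# Gelman-Rubin potential scale reduction factor from a list of chains
psrf <- function(draws) {
  m <- length(draws)
  if (m < 2) return(NA_real_)
  n <- length(draws[[1]])
  means <- vapply(draws, mean, numeric(1))
  vars <- vapply(draws, var, numeric(1))
  B <- n * var(means)
  Wv <- mean(vars)
  if (Wv == 0) return(1)
  sqrt(((n - 1) / n * Wv + B / n) / Wv)
}

car_diagnostics <- function(fit) {
  beta_draws <- post_burn(fit, "beta")
  terms <- fit$terms
  psrf_beta <- vapply(seq_along(terms), function(j) {
    psrf(lapply(beta_draws, function(b) b[, j]))
  }, numeric(1))
  psrf_rho <- psrf(post_burn(fit, "rho"))
  psrf_logtau2 <- psrf(lapply(post_burn(fit, "tau2"), log))
  acc <- lapply(fit$chains, function(ch) ch$accept)
  tibble(
    parameter = c(terms, "rho", "log_tau2"),
    psrf = c(psrf_beta, psrf_rho, psrf_logtau2),
    accept_rate = c(
      rowMeans(vapply(acc, function(a) a$beta, numeric(length(terms)))),
      mean(vapply(acc, function(a) a$rho, numeric(1))),
      NA_real_
    )
  )
}

#' Posterior odds ratios from a CAR fit
#'
#' Exponentiates the pooled post-burn-in draws of the fixed effects and
#' summarises each covariate by the posterior median and central credible
#' interval of the odds ratio.
#'
#' @param fit A `car_fit`.
#' @param conf_level Credible level (default 0.95).
#' @param include_intercept Keep the intercept row?
#' @return Tibble: `term`, `or`, `conf.low`, `conf.high`.
#' @export
extract_or <- function(fit, conf_level = 0.95, include_intercept = FALSE) {
  draws <- pooled_beta(fit)
  if (nrow(draws) == 0) abort("no post-burn-in draws available.")
  a <- (1 - conf_level) / 2
  or_draws <- exp(draws)
  out <- tibble(
    term = colnames(or_draws),
    or = unname(apply(or_draws, 2, median)),
    conf.low = unname(apply(or_draws, 2, quantile, probs = a)),
    conf.high = unname(apply(or_draws, 2, quantile, probs = 1 - a))
  )
  if (!include_intercept) out <- out[out$term != "(Intercept)", , drop = FALSE]
  out
}

#' @method print car_fit
#' @export
print.car_fit <- function(x, ...) {
  cat(sprintf(
    "Binomial Leroux CAR fit: n = %d, %d chain(s) x %d iterations (burn-in %d)\n",
    x$n, x$n_chains, x$n_iter, x$burn_in))
  cat(sprintf("max PSRF = %.3f\n", max(x$diagnostics$psrf, na.rm = TRUE)))
  cat("\nPosterior odds ratios (median and credible interval):\n")
  print(x$or_summary)
  invisible(x)
}

#' @export
tidy.car_fit <- function(x, exponentiate = TRUE, include_intercept = FALSE, ...) {
  if (exponentiate) {
    out <- extract_or(x, conf_level = x$conf_level,
                      include_intercept = include_intercept)
    dplyr::rename(out, estimate = "or")
  } else {
    draws <- pooled_beta(x)
    a <- (1 - x$conf_level) / 2
    out <- tibble(
      term = colnames(draws),
      estimate = unname(apply(draws, 2, median)),
      conf.low = unname(apply(draws, 2, quantile, probs = a)),
      conf.high = unname(apply(draws, 2, quantile, probs = 1 - a))
    )
    if (!include_intercept) out <- out[out$term != "(Intercept)", , drop = FALSE]
    out
  }
}

#' @export
glance.car_fit <- function(x, ...) {
  tibble(
    n = x$n, n_chains = x$n_chains, n_iter = x$n_iter, burn_in = x$burn_in,
    n_draws = x$n_chains * (x$n_iter - x$burn_in),
    max_psrf = max(x$diagnostics$psrf, na.rm = TRUE),
    rho_median = median(unlist(post_burn(x, "rho"))),
    tau2_median = median(unlist(post_burn(x, "tau2")))
  )
}

#' @export
autoplot.car_fit <- function(object, ...) {
  or <- object$or_summary
  or$term <- factor(or$term, levels = rev(or$term))
  ggplot2::ggplot(or, ggplot2::aes(x = .data$or, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "odds ratio (posterior median, 95% CrI)", y = NULL)
}
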