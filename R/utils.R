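#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, restoring the caller's
#' RNG state afterwards. All generators in the package route their randomness
#' through this helper so that no call leaks state into the session.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single non-missing integer.")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic stream splitting: one master seed fans out to named stages so
# that changing, say, the wind draw does not perturb the demographics draw.
derive_seed <- function(seed, offset) {
  s <- (as.double(seed) %% 2147483647) * 48271 + 10007 * as.double(offset)
  as.integer(s %% 2147483647)
}

#' Minimal absolute circular difference between two angles in degrees
#' @param a,b Angles in degrees.
#' @return Difference in `[0, 180]`.
#' @keywords internal
circular_diff <- function(a, b) {
  d <- abs((a - b) %% 360)
  pmin(d, 360 - d)
}

check_number <- function(x, name, min = -Inf, max = Inf,
                         strict_min = FALSE, integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single non-missing number.", name))
  }
  if (integerish && x != round(x)) {
    abort(sprintf("`%s` must be a whole number.", name))
  }
  if (strict_min && x <= min) {
    abort(sprintf("`%s` must be > %s.", name, format(min)))
  }
  if (!strict_min && x < min) {
    abort(sprintf("`%s` must be >= %s.", name, format(min)))
  }
  if (x > max) {
    abort(sprintf("`%s` must be <= %s.", name, format(max)))
  }
  invisible(x)
}

check_columns <- function(df, cols, name) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("`%s` is missing required column(s): %s.",
                  name, paste(missing, collapse = ", ")))
  }
  invisible(df)
}
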