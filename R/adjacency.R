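#' Queen-contiguity adjacency from block-group polygons
#'
#' Two block groups are neighbors when their polygons share at least one
#' boundary point — an edge or a single corner (the queen criterion).
#' Detection is geometric: vertices are snapped to a `tol` grid and hashed,
#' so polygons sharing a vertex are neighbors; a second pass catches
#' T-junctions where a vertex of one polygon lies in the interior of
#' another's edge (candidate pairs limited to overlapping bounding boxes).
#' Block groups with no neighbor are dropped and reported.
#'
#' @param block_groups Block-group tibble with `block_group_id` and a
#'   `geometry` list-column of polygon rings.
#' @param tol Snap tolerance for coordinate comparison.
#' @return Object of class `queen_adjacency`: list with `W` (symmetric 0/1
#'   sparse matrix over the retained block groups, zero diagonal), `ids`
#'   (retained ids, in input order), and `dropped_ids`.
#' @export
#' @examples
#' region <- generate_region(region_spec(2, 2, 1, seed = 1))
#' adj <- build_queen_adjacency(region)
#' Matrix::rowSums(adj$W) # each corner cell touches the other three
build_queen_adjacency <- function(block_groups, tol = 1e-8) {
  check_columns(block_groups, c("block_group_id", "geometry"), "block_groups")
  n <- nrow(block_groups)
  ids <- block_groups$block_group_id
  geoms <- block_groups$geometry
  for (i in seq_len(n)) {
    g <- geoms[[i]]
    if (!is.matrix(g) || ncol(g) != 2 || nrow(g) < 3 || any(!is.finite(g))) {
      abort(sprintf("invalid polygon geometry for block group %s.", ids[i]))
    }
  }

  # open rings of snapped vertices
  verts <- lapply(geoms, function(g) {
    g <- close_ring(g)
    unique(round(g[-nrow(g), , drop = FALSE] / tol) * tol)
  })

  # pass 1: shared snapped vertex
  key <- lapply(verts, function(v) paste(v[, 1], v[, 2], sep = "_"))
  vert_map <- split(rep(seq_len(n), lengths(key)), unlist(key))
  pairs_i <- integer(0); pairs_j <- integer(0)
  for (polys in vert_map) {
    if (length(polys) < 2) next
    cmb <- utils::combn(sort(unique(polys)), 2)
    pairs_i <- c(pairs_i, cmb[1, ]); pairs_j <- c(pairs_j, cmb[2, ])
  }

  # pass 2: vertex-on-edge contact between bbox-overlapping pairs
  bbox <- t(vapply(verts, function(v) {
    c(min(v[, 1]), max(v[, 1]), min(v[, 2]), max(v[, 2]))
  }, numeric(4)))
  ord <- order(bbox[, 1])
  for (a in seq_len(n - 1L)) {
    i <- ord[a]
    for (b in (a + 1L):n) {
      j <- ord[b]
      if (bbox[j, 1] > bbox[i, 2] + tol) break
      if (bbox[j, 3] > bbox[i, 4] + tol || bbox[i, 3] > bbox[j, 4] + tol) next
      if (shares_boundary_point(verts[[i]], verts[[j]],
                                geoms[[i]], geoms[[j]], tol)) {
        pairs_i <- c(pairs_i, min(i, j)); pairs_j <- c(pairs_j, max(i, j))
      }
    }
  }

  W <- Matrix::sparseMatrix(i = c(pairs_i, pairs_j), j = c(pairs_j, pairs_i),
                            x = 1, dims = c(n, n), use.last.ij = TRUE)
  W@x[] <- 1
  deg <- Matrix::rowSums(W)
  dropped <- ids[deg == 0]
  keep <- deg > 0
  structure(
    list(W = W[keep, keep, drop = FALSE], ids = ids[keep],
         dropped_ids = dropped, n = sum(keep)),
    class = "queen_adjacency"
  )
}

# any vertex of one polygon on an edge of the other (or shared vertex)
shares_boundary_point <- function(va, vb, ga, gb, tol) {
  vertex_on_edges <- function(v, g) {
    g <- close_ring(g)
    for (p in seq_len(nrow(v))) {
      for (e in seq_len(nrow(g) - 1L)) {
        if (point_segment_distance(v[p, 1], v[p, 2], g[e, 1], g[e, 2],
                                   g[e + 1L, 1], g[e + 1L, 2]) <= tol) {
          return(TRUE)
        }
      }
    }
    FALSE
  }
  vertex_on_edges(va, gb) || vertex_on_edges(vb, ga)
}

#' @method print queen_adjacency
#' @export
print.queen_adjacency <- function(x, ...) {
  cat(sprintf("<queen_adjacency> %d block groups, %d dropped isolate(s), %d edges\n",
              x$n, length(x$dropped_ids), sum(x$W) / 2))
  invisible(x)
}

#' Moran's I with permutation inference
#'
#' Computes `I = (n / S0) * (z' W z) / (z' z)` with `z` the centered values
#' and `S0` the sum of all weights, its null expectation `-1 / (n - 1)`, and
#' a two-sided permutation p-value from random relabelings of the values
#' over the areal units.
#'
#' @param values Numeric vector over the areal units (at least two distinct
#'   values).
#' @param W A `queen_adjacency` object or adjacency/weights matrix.
#' @param n_permutations Number of random relabelings (>= 999 recommended).
#' @param seed Integer seed.
#' @return Object of class `moran_test`: list with `statistic`, `expected`,
#'   `p_value`, `n`, `n_permutations`, and the permutation draws `sims`.
#' @export
morans_i <- function(values, W, n_permutations = 999, seed = 1) {
  W <- as_adjacency_matrix(W)
  n <- length(values)
  if (n != nrow(W)) abort("`values` must align with `W`.")
  if (length(unique(values)) < 2) {
    abort("zero variance: Moran's I requires at least two distinct values.")
  }
  check_number(n_permutations, "n_permutations", min = 1, integerish = TRUE)

  z <- values - mean(values)
  s0 <- sum(W)
  denom <- sum(z^2)
  i_obs <- (n / s0) * as.numeric(z %*% (W %*% z)) / denom
  expected <- -1 / (n - 1)

  sims <- with_seed(derive_seed(seed, 8), {
    Zp <- vapply(seq_len(n_permutations),
                 function(k) z[sample.int(n)], numeric(n))
    WZ <- as.matrix(W %*% Zp)
    (n / s0) * colSums(Zp * WZ) / denom
  })
  p_greater <- (1 + sum(sims >= i_obs)) / (n_permutations + 1)
  p_less <- (1 + sum(sims <= i_obs)) / (n_permutations + 1)
  p <- min(1, 2 * min(p_greater, p_less))

  structure(list(statistic = i_obs, expected = expected, p_value = p,
                 n = n, n_permutations = n_permutations, sims = sims),
            class = "moran_test")
}

#' @method print moran_test
#' @export
print.moran_test <- function(x, ...) {
  cat(sprintf("Moran's I = %.4f (expected %.4f under no autocorrelation)\n",
              x$statistic, x$expected))
  cat(sprintf("two-sided permutation p = %.4g (%d permutations, n = %d)\n",
              x$p_value, x$n_permutations, x$n))
  invisible(x)
}

#' @export
tidy.moran_test <- function(x, ...) {
  tibble(statistic = x$statistic, expected = x$expected,
         p.value = x$p_value, n = x$n, n_permutations = x$n_permutations)
}

#' @export
autoplot.moran_test <- function(object, ...) {
  df <- tibble(sims = object$sims)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sims)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$statistic, colour = "red") +
    ggplot2::geom_vline(xintercept = object$expected, linetype = 2) +
    ggplot2::labs(x = "Moran's I under permutation", y = "count",
                  title = sprintf("Observed I = %.3f, p = %.3g",
                                  object$statistic, object$p_value))
}
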