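# Neighborhood interaction testing. Two voxels interact when their centers
# lie within `radius` pixels (Euclidean, 3D). Observed unordered interacting
# pair counts per label pair are compared against a null built by shuffling
# the cluster annotation over the voxels: one-sided permutation p-values on
# either tail and log2 enrichment of observed over mean permuted counts.
# The neighbor-pair set depends only on geometry, so it is built once and
# only the label counting is repeated per permutation.

#' Euclidean distance between two 3D points
#'
#' @param a,b Length-3 coordinate vectors `(x, y, z)`.
#' @return `sqrt((x1-x0)^2 + (y1-y0)^2 + (z1-z0)^2)`.
#' @export
pairwise_distance <- function(a, b) {
  sqrt(sum((as.numeric(a) - as.numeric(b))^2))
}

#' All voxel pairs within an interaction radius
#'
#' kd-tree radius search (candidates) followed by an exact Euclidean
#' distance filter, so the pair set is identical to a brute-force
#' all-pairs scan with `dist <= radius`.
#'
#' @param coords n x 3 matrix of voxel centers `(x, y, z)` in pixels.
#' @param radius Interaction radius in pixels, > 0.
#' @return Two-column integer matrix of pairs `(i, j)` with `i < j`.
#' @export
neighbor_pairs <- function(coords, radius) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (radius <= 0) stopf("`radius` must be > 0")
  k <- min(n, 64L)
  repeat {
    nn <- RANN::nn2(coords, coords, k = k, searchtype = "radius",
                    radius = radius * (1 + 1e-9) + 1e-9)
    saturated <- nn$nn.idx[, k] != 0L
    if (!any(saturated) || k == n) break
    k <- min(n, 2L * k)
  }
  i <- rep(seq_len(n), times = k)
  j <- as.vector(nn$nn.idx)
  keep <- j != 0L & j > i
  i <- i[keep]; j <- j[keep]
  d2 <- rowSums((coords[i, , drop = FALSE] - coords[j, , drop = FALSE])^2)
  keep <- sqrt(d2) <= radius
  cbind(i = i[keep], j = j[keep])
}

count_pairs <- function(li, lj, K) {
  lo <- pmin(li, lj); hi <- pmax(li, lj)
  cnt <- tabulate((hi - 1L) * K + lo, nbins = K * K)
  U <- matrix(cnt, K, K)          # upper-triangle (lo row, hi col) counts
  U + t(U) - diag(diag(U), K)
}

#' Count neighborhood interactions
#'
#' Entry `(A, B)` is the number of unordered voxel pairs within `radius`
#' whose labels are `{A, B}`; the diagonal counts same-label pairs, each
#' pair once. The matrix is symmetric by construction.
#'
#' @param coords n x 3 voxel centers `(x, y, z)`.
#' @param labels Cluster labels (factor or integer), length n.
#' @param radius Interaction radius in pixels (default 5).
#' @param pairs Optional precomputed [neighbor_pairs()] matrix.
#' @return K x K symmetric integer matrix with label dimnames.
#' @export
count_interactions <- function(coords, labels, radius = 5, pairs = NULL) {
  if (nrow(as.matrix(coords)) != length(labels)) {
    stopf("coords and labels length mismatch")
  }
  f <- as.factor(labels)
  K <- nlevels(f)
  li <- as.integer(f)
  pairs <- pairs %||% neighbor_pairs(coords, radius)
  M <- count_pairs(li[pairs[, 1]], li[pairs[, 2]], K)
  dimnames(M) <- list(levels(f), levels(f))
  M
}

#' Permutation test of neighborhood interaction enrichment
#'
#' Builds the radius neighbor-pair set once, then for each of `n_perm`
#' uniform random permutations of the labels recounts the K x K interaction
#' matrix. One-sided p-values use strict inequalities with the +1
#' correction, `p = (#{permuted > observed} + 1) / (n_perm + 1)` (ties count
#' toward neither tail, so the minimum attainable p is `1/(n_perm+1)`).
#' Enrichment is `log2(observed / mean(permuted))`, `NaN` where either side
#' is zero. Deterministic given `seed`.
#'
#' @inheritParams count_interactions
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed for the permutation stream.
#' @return An `interaction_result`: `real_counts`, `perm_mean`,
#'   `log2_enrichment`, `p_greater`, `p_less`, `n_perm`, `radius`,
#'   `levels`.
#' @export
permutation_test <- function(coords, labels, radius = 5, n_perm = 1000,
                             seed = 1L, pairs = NULL) {
  coords <- as.matrix(coords)
  if (nrow(coords) != length(labels)) stopf("coords and labels length mismatch")
  if (n_perm < 1L) stopf("`n_perm` must be >= 1")
  f <- as.factor(labels)
  if (nlevels(f) < 2L) stopf("need at least 2 distinct labels")
  K <- nlevels(f)
  li <- as.integer(f)
  pairs <- pairs %||% neighbor_pairs(coords, radius)
  real <- count_pairs(li[pairs[, 1]], li[pairs[, 2]], K)

  gt <- matrix(0L, K, K); lt <- matrix(0L, K, K); acc <- matrix(0, K, K)
  with_seed(seed, {
    for (p in seq_len(n_perm)) {
      perm <- sample(li)
      M <- count_pairs(perm[pairs[, 1]], perm[pairs[, 2]], K)
      gt <- gt + (M > real)
      lt <- lt + (M < real)
      acc <- acc + M
    }
  })
  perm_mean <- acc / n_perm
  enr <- log2(real / perm_mean)
  enr[real == 0 | perm_mean == 0] <- NaN
  dn <- list(levels(f), levels(f))
  structure(
    list(real_counts = `dimnames<-`(real, dn),
         perm_mean = `dimnames<-`(perm_mean, dn),
         log2_enrichment = `dimnames<-`(enr, dn),
         p_greater = `dimnames<-`((gt + 1) / (n_perm + 1), dn),
         p_less = `dimnames<-`((lt + 1) / (n_perm + 1), dn),
         n_perm = n_perm, radius = radius, levels = levels(f)),
    class = "interaction_result"
  )
}

#' @export
print.interaction_result <- function(x, ...) {
  cat(sprintf("interaction_result: %d neighborhoods, radius %g px, %d permutations\n",
              length(x$levels), x$radius, x$n_perm))
  cat("log2 enrichment:\n")
  print(round(x$log2_enrichment, 3))
  invisible(x)
}

#' Long-form interaction results table
#'
#' One row per unordered label pair: observed count, permutation mean,
#' log2 enrichment, and both one-sided p-values.
#'
#' @param result An `interaction_result`.
#' @export
interaction_table <- function(result) {
  K <- length(result$levels)
  ut <- which(upper.tri(result$real_counts, diag = TRUE), arr.ind = TRUE)
  data.frame(
    a = result$levels[ut[, 1]], b = result$levels[ut[, 2]],
    real = result$real_counts[ut],
    perm_mean = result$perm_mean[ut],
    log2_enrichment = result$log2_enrichment[ut],
    p_greater = result$p_greater[ut],
    p_less = result$p_less[ut],
    stringsAsFactors = FALSE
  )
}

#' Statistically significant interaction edges
#'
#' Edges with `p_greater < alpha` (enriched, sign `+1`) or `p_less < alpha`
#' (depleted, sign `-1`); edge weight is the log2 enrichment.
#'
#' @param result An `interaction_result`.
#' @param alpha One-sided significance level (default 0.05).
#' @return Data.frame `a, b, sign, weight, p`.
#' @export
significant_edges <- function(result, alpha = 0.05) {
  tab <- interaction_table(result)
  enriched <- tab[tab$p_greater < alpha, , drop = FALSE]
  depleted <- tab[tab$p_less < alpha, , drop = FALSE]
  out <- rbind(
    if (nrow(enriched)) data.frame(a = enriched$a, b = enriched$b, sign = 1L,
                                   weight = enriched$log2_enrichment,
                                   p = enriched$p_greater),
    if (nrow(depleted)) data.frame(a = depleted$a, b = depleted$b, sign = -1L,
                                   weight = depleted$log2_enrichment,
                                   p = depleted$p_less)
  )
  if (is.null(out)) out <- data.frame(a = character(0), b = character(0),
                                      sign = integer(0), weight = numeric(0),
                                      p = numeric(0))
  rownames(out) <- NULL
  out
}

#' Export significant edges as a graph
#'
#' @param result An `interaction_result`.
#' @param path Output path (`.graphml` or `.dot`).
#' @param alpha Significance level.
#' @export
write_interaction_graph <- function(result, path, alpha = 0.05) {
  edges <- significant_edges(result, alpha)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = result$levels))
  fmt <- if (grepl("\\.dot$", path)) "dot" else "graphml"
  igraph::write_graph(g, path, format = fmt)
  invisible(path)
}

#' Per-FOV permutation tests
#'
#' Shuffles labels within each FOV separately (never across FOVs) and
#' returns one `interaction_result` per FOV.
#'
#' @param table Voxel table with `fov_id, x, y, z`.
#' @param labels Labels aligned with rows.
#' @inheritParams permutation_test
#' @export
permutation_test_by_fov <- function(table, labels, radius = 5, n_perm = 1000,
                                    seed = 1L) {
  f <- as.factor(labels)
  groups <- split(seq_len(nrow(table)), table$fov_id)
  res <- lapply(seq_along(groups), function(gi) {
    ix <- groups[[gi]]
    permutation_test(as.matrix(table[ix, c("x", "y", "z")]),
                     factor(f[ix], levels = levels(f)),
                     radius = radius, n_perm = n_perm, seed = seed + gi)
  })
  names(res) <- names(groups)
  res
}
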