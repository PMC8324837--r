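# Neighborhood identification: agglomerative clustering of voxel features
# (Ward linkage by default), optional Barnes-Hut t-SNE embedding with
# clustering on the 2D plane, profile summaries, reproducible merging of
# clusters, and rendering of label maps back into the image frame.

#' Agglomerative clustering of voxel features
#'
#' @param features Numeric matrix or voxel table (channel columns used).
#' @param k Number of clusters to cut, `1 <= k <= n`.
#' @param linkage Linkage method for [stats::hclust()] (default `"ward.D2"`).
#' @param metric Distance metric for [stats::dist()] (default `"euclidean"`).
#' @return Integer cluster labels (1..k), deterministic for a fixed input
#'   order.
#' @export
hierarchical_cluster <- function(features, k, linkage = "ward.D2",
                                 metric = "euclidean") {
  m <- as_feature_matrix(features)
  if (k < 1L || k > nrow(m)) stopf("k = %d outside [1, %d]", k, nrow(m))
  if (k == 1L) return(rep(1L, nrow(m)))
  hc <- stats::hclust(stats::dist(m, method = metric), method = linkage)
  as.integer(stats::cutree(hc, k = k))
}

as_feature_matrix <- function(features, channels = NULL) {
  if (is.matrix(features)) return(features)
  ch <- channels %||% voxel_channels(features)
  as.matrix(features[, ch, drop = FALSE])
}

#' Barnes-Hut t-SNE embedding
#'
#' @param features Numeric matrix or voxel table.
#' @param perplexity t-SNE perplexity (default 30); requires
#'   `n > 3 * perplexity`.
#' @param seed Integer seed; the embedding is deterministic given the seed.
#' @param max_iter Iterations (default 1000).
#' @return n x 2 coordinate matrix.
#' @export
embed_tsne <- function(features, perplexity = 30, seed = 1L, max_iter = 1000) {
  m <- as_feature_matrix(features)
  if (nrow(m) <= 3 * perplexity) {
    stopf("perplexity %g too large for n = %d (need n > 3*perplexity)",
          perplexity, nrow(m))
  }
  with_seed(seed, {
    Rtsne::Rtsne(m, perplexity = perplexity, max_iter = max_iter,
                 check_duplicates = FALSE, pca = FALSE, verbose = FALSE,
                 num_threads = 1)$Y
  })
}

#' Hierarchical clustering on a 2D embedding
#'
#' Euclidean-distance agglomerative clustering of the t-SNE plane, used to
#' over-segment the embedding (default 40 clusters) before merging.
#'
#' @param coords n x 2 embedding coordinates.
#' @param k Number of clusters (default 40).
#' @param linkage Linkage method (default `"ward.D2"`).
#' @export
cluster_on_embedding <- function(coords, k = 40, linkage = "ward.D2") {
  hierarchical_cluster(as.matrix(coords), k = k, linkage = linkage,
                       metric = "euclidean")
}

#' Merge clusters according to a map
#'
#' @param labels Integer cluster labels.
#' @param merge_map Named vector or list mapping every observed initial
#'   label to its final label.
#' @return Relabeled integer vector.
#' @export
merge_clusters <- function(labels, merge_map) {
  map <- unlist(merge_map)
  if (is.null(names(map))) names(map) <- seq_along(map)
  obs <- unique(labels)
  miss <- setdiff(as.character(obs), names(map))
  if (length(miss)) stopf("merge map lacks entries for labels: %s",
                          paste(miss, collapse = ", "))
  as.integer(map[as.character(labels)])
}

#' Automatic profile-based merge map
#'
#' Reproducible stand-in for manual annotation: Ward clustering of the
#' initial cluster profiles (Euclidean distance) down to `k_final` groups.
#' Euclidean distance is used rather than profile correlation because
#' correlation is undefined, and numerically arbitrary, for the
#' near-constant profiles that clipping normalizations produce (e.g. a
#' uniformly low cytoplasmic cluster).
#'
#' @param profiles Initial cluster x channel profile matrix.
#' @param k_final Requested number of final clusters.
#' @return Named integer vector, initial label -> final label.
#' @export
merge_map_from_profiles <- function(profiles, k_final) {
  if (k_final > nrow(profiles)) stopf("k_final exceeds number of clusters")
  hc <- stats::hclust(stats::dist(profiles), method = "ward.D2")
  map <- stats::cutree(hc, k = k_final)
  names(map) <- rownames(profiles)
  map
}

#' Per-cluster marker profiles
#'
#' @param table Voxel table (channel columns summarized).
#' @param labels Cluster labels aligned with the rows.
#' @param stat `"mean"` or `"median"`.
#' @param row_normalize `"none"` or `"zscore"` (z-score each cluster row
#'   across channels, as in expression heatmaps).
#' @return cluster x channel matrix with cluster ids as rownames.
#' @export
cluster_profile <- function(table, labels, stat = c("mean", "median"),
                            row_normalize = c("none", "zscore")) {
  stat <- match.arg(stat)
  row_normalize <- match.arg(row_normalize)
  if (length(labels) != nrow(table)) stopf("labels do not align with table rows")
  m <- as_feature_matrix(table)
  ids <- sort(unique(labels))
  fun <- if (stat == "mean") colMeans else function(x) apply(x, 2, stats::median)
  prof <- t(vapply(ids, function(id) fun(m[labels == id, , drop = FALSE]),
                   numeric(ncol(m))))
  rownames(prof) <- ids
  colnames(prof) <- colnames(m)
  if (row_normalize == "zscore") {
    prof <- t(apply(prof, 1, function(r) {
      s <- sqrt(mean((r - mean(r))^2))
      if (s == 0) r * 0 else (r - mean(r)) / s
    }))
  }
  prof
}

#' Polygon gate on an embedding
#'
#' Selects points inside or on the boundary of a polygon, emulating manual
#' gating of pixel/voxel groups on a 2D map. Even-odd ray casting with an
#' explicit on-boundary test, so boundary points are included.
#'
#' @param coords n x 2 point coordinates.
#' @param polygon m x 2 vertex matrix (m >= 3), in order.
#' @return Logical vector of length n.
#' @export
gate_embedding <- function(coords, polygon) {
  coords <- as.matrix(coords); polygon <- as.matrix(polygon)
  if (nrow(polygon) < 3L) stopf("polygon needs at least 3 vertices")
  if (nrow(unique(polygon)) < 3L) stopf("degenerate polygon")
  px <- polygon[, 1]; py <- polygon[, 2]
  nxt <- c(seq_len(nrow(polygon))[-1], 1L)
  vapply(seq_len(nrow(coords)), function(i) {
    x <- coords[i, 1]; y <- coords[i, 2]
    inside <- FALSE
    for (j in seq_len(nrow(polygon))) {
      x1 <- px[j]; y1 <- py[j]; x2 <- px[nxt[j]]; y2 <- py[nxt[j]]
      # on-segment check
      cross <- (x - x1) * (y2 - y1) - (y - y1) * (x2 - x1)
      if (abs(cross) < 1e-12 &&
          x >= min(x1, x2) - 1e-12 && x <= max(x1, x2) + 1e-12 &&
          y >= min(y1, y2) - 1e-12 && y <= max(y1, y2) + 1e-12) {
        return(TRUE)
      }
      if ((y1 > y) != (y2 > y)) {
        xint <- x1 + (y - y1) / (y2 - y1) * (x2 - x1)
        if (x < xint) inside <- !inside
      }
    }
    inside
  }, logical(1))
}

#' Render voxel labels back into the image frame
#'
#' Paints each voxel's window footprint with its cluster label; unassigned
#' pixels are 0. In `projection_xy` mode z is collapsed and overlapping
#' footprints resolved by majority label per pixel; in `volume` mode a 3D
#' label volume is returned (later voxels overwrite earlier ones where
#' footprints overlap).
#'
#' @param table Voxel table with original-frame centers and window attr.
#' @param labels Integer labels aligned with rows.
#' @param frame_dims `(n_z, n_y, n_x)` of the original frame.
#' @param mode `"projection_xy"` or `"volume"`.
#' @return Integer `[y, x]` matrix or `[z, y, x]` array.
#' @export
render_neighborhood_map <- function(table, labels, frame_dims,
                                    mode = c("projection_xy", "volume")) {
  mode <- match.arg(mode)
  w <- attr(table, "window") %||% c(1, 1, 1)
  half <- (w - 1) / 2
  x0 <- round(table$x - half[1]); x1 <- x0 + w[1] - 1L
  y0 <- round(table$y - half[2]); y1 <- y0 + w[2] - 1L
  z0 <- round(table$z - half[3]); z1 <- z0 + w[3] - 1L
  if (any(x0 < 0 | y0 < 0 | z0 < 0) ||
      any(x1 >= frame_dims[3] | y1 >= frame_dims[2] | z1 >= frame_dims[1])) {
    stopf("voxel footprints fall outside the frame")
  }
  K <- max(labels)
  if (mode == "projection_xy") {
    votes <- array(0L, dim = c(frame_dims[2], frame_dims[3], K))
    for (i in seq_len(nrow(table))) {
      ys <- (y0[i] + 1L):(y1[i] + 1L); xs <- (x0[i] + 1L):(x1[i] + 1L)
      votes[ys, xs, labels[i]] <- votes[ys, xs, labels[i]] + (z1[i] - z0[i] + 1L)
    }
    tot <- rowSums(votes, dims = 2)
    out <- apply(votes, c(1, 2), which.max)
    out[tot == 0] <- 0L
    matrix(as.integer(out), frame_dims[2], frame_dims[3])
  } else {
    out <- array(0L, dim = frame_dims)
    for (i in seq_len(nrow(table))) {
      out[(z0[i] + 1L):(z1[i] + 1L), (y0[i] + 1L):(y1[i] + 1L),
          (x0[i] + 1L):(x1[i] + 1L)] <- labels[i]
    }
    out
  }
}
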