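# Small figure helpers. Heatmaps delegate to pheatmap when available.

#' Neighborhood profile heatmap
#'
#' Row-z-scored cluster x channel heatmap of marker profiles.
#'
#' @param profiles Matrix from [cluster_profile()].
#' @param path Output PNG path.
#' @export
plot_profile_heatmap <- function(profiles, path) {
  z <- t(apply(profiles, 1, function(r) {
    s <- sqrt(mean((r - mean(r))^2))
    if (s == 0) r * 0 else (r - mean(r)) / s
  }))
  if (requireNamespace("pheatmap", quietly = TRUE)) {
    pheatmap::pheatmap(z, filename = path, cluster_cols = FALSE)
  } else {
    grDevices::png(path, width = 640, height = 480)
    on.exit(grDevices::dev.off())
    graphics::image(t(z[rev(seq_len(nrow(z))), , drop = FALSE]),
                    axes = FALSE, main = "neighborhood profiles")
  }
  invisible(path)
}

#' Embedding scatter colored by neighborhood
#'
#' @param coords n x 2 embedding coordinates.
#' @param labels Cluster labels.
#' @param path Output PNG path.
#' @export
plot_embedding <- function(coords, labels, path) {
  grDevices::png(path, width = 640, height = 640)
  on.exit(grDevices::dev.off())
  graphics::plot(coords[, 1], coords[, 2], col = as.integer(as.factor(labels)),
                 pch = 16, cex = 0.4, xlab = "tSNE 1", ylab = "tSNE 2")
  invisible(path)
}

#' Per-neighborhood channel distribution boxplot
#'
#' @param dist Output of [channel_distribution_by_neighborhood()].
#' @param path Output PNG path.
#' @param main Plot title.
#' @export
plot_channel_distribution <- function(dist, path, main = "") {
  grDevices::png(path, width = 640, height = 480)
  on.exit(grDevices::dev.off())
  graphics::boxplot(dist$values, main = main, xlab = "neighborhood",
                    ylab = "counts")
  invisible(path)
}
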