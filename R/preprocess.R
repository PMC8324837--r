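# Denoising and masking. Low-current iterative acquisitions are sparse:
# true signal is spatially dense while noise is scattered, so pixels are
# kept or discarded based on the mean distance to their k nearest positive
# neighbors on the plane-summed image, not on intensity.

#' Sum a channel stack over a z-range
#'
#' @param stack A [channel_stack()] or a 3D array `[z, y, x]`.
#' @param z_range Integer vector of 1-based plane indices (default: all).
#' @return 2D matrix `[y, x]` of per-pixel sums.
#' @export
sum_planes <- function(stack, z_range = NULL) {
  data <- if (inherits(stack, "channel_stack")) stack$data else stack
  nz <- dim(data)[1]
  z_range <- z_range %||% seq_len(nz)
  if (length(z_range) == 0L) stopf("empty z_range")
  if (any(z_range < 1L | z_range > nz)) stopf("z_range outside stack depth %d", nz)
  if (length(z_range) == 1L) return(data[z_range, , , drop = TRUE])
  colSums(data[z_range, , , drop = FALSE], dims = 1)
}

#' k-nearest-neighbor density mask
#'
#' For each positive pixel (summed count > 0) of a 2D image, computes the
#' mean Euclidean distance to its `k` nearest other positive pixels; the
#' mask keeps exactly the positive pixels whose mean distance is <= `cutoff`.
#' Negative (zero-count) pixels are always excluded.
#'
#' @param image2d 2D count image (e.g. from [sum_planes()]).
#' @param k Number of neighbors (default 25).
#' @param cutoff Distance cutoff in pixels; if `NULL`, taken from
#'   [suggest_knn_cutoff()] (the Otsu valley between the dense-signal and
#'   sparse-noise modes of the distance distribution).
#' @param channel Channel name, used in error messages.
#' @return Logical matrix of the same shape.
#' @export
knn_density_mask <- function(image2d, k = 25, cutoff = NULL, channel = "channel") {
  pos <- which(image2d > 0, arr.ind = TRUE)  # (row=y, col=x)
  if (nrow(pos) < k + 1L) {
    stopf("channel '%s': only %d positive pixels, need at least k+1 = %d",
          channel, nrow(pos), k + 1L)
  }
  nn <- RANN::nn2(pos, pos, k = k + 1L)       # first neighbor is the pixel itself
  mean_d <- rowMeans(nn$nn.dists[, -1L, drop = FALSE])
  cutoff <- cutoff %||% suggest_knn_cutoff(mean_d)
  mask <- matrix(FALSE, nrow(image2d), ncol(image2d))
  keep <- mean_d <= cutoff
  mask[pos[keep, , drop = FALSE]] <- TRUE
  mask
}

#' Suggest a kNN-distance cutoff by Otsu thresholding
#'
#' The mean-kNN-distance histogram of a sparse acquisition is bimodal:
#' dense true signal at small distances, scattered noise at large ones.
#' The Otsu threshold between the two modes is a reasonable default cutoff.
#'
#' @param mean_dists Mean kNN distances of the positive pixels.
#' @return A single cutoff value (same units, pixels).
#' @export
suggest_knn_cutoff <- function(mean_dists) {
  rng <- range(mean_dists)
  if (diff(rng) == 0) return(rng[1])
  scaled <- (mean_dists - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(matrix(scaled, ncol = 1)), range = c(0, 1))
  rng[1] + thr * diff(rng)
}

#' Apply a 2D mask to every z-plane of a stack
#'
#' @param stack A [channel_stack()] or 3D array.
#' @param mask Logical `[y, x]` matrix matching the plane dimensions.
#' @return Same type as the input, with values outside the mask zeroed in
#'   every plane.
#' @export
apply_mask_per_plane <- function(stack, mask) {
  data <- if (inherits(stack, "channel_stack")) stack$data else stack
  d <- dim(data)
  if (!identical(dim(mask), d[2:3])) {
    stopf("mask dims (%s) do not match plane dims (%s)",
          paste(dim(mask), collapse = "x"), paste(d[2:3], collapse = "x"))
  }
  keep <- aperm(array(mask, dim = c(d[2], d[3], d[1])), c(3, 1, 2))
  out <- data * keep
  if (inherits(stack, "channel_stack")) channel_stack(stack$channel, stack$marker, out)
  else out
}

#' Denoise a volume with the kNN density filter
#'
#' Convenience wrapper: per channel, sums the selected planes, builds the
#' [knn_density_mask()], and applies it to every plane.
#'
#' @param volume A `multiplex_volume`.
#' @param channels Channels to denoise (default: all).
#' @param k,cutoffs `k` and optional named per-channel cutoff vector.
#' @param z_range Planes summed to build the mask (default: all).
#' @return The denoised `multiplex_volume`.
#' @export
denoise_volume <- function(volume, channels = vol_channels(volume), k = 25,
                           cutoffs = NULL, z_range = NULL) {
  for (ch in channels) {
    img <- sum_planes(volume$stacks[[ch]], z_range)
    mask <- knn_density_mask(img, k = k, cutoff = cutoffs[[ch]], channel = ch)
    volume$stacks[[ch]] <- apply_mask_per_plane(volume$stacks[[ch]], mask)
  }
  volume
}

#' Trim a pixel border from the lateral axes
#'
#' Discards `n_pixels` around each lateral border (z untouched) to avoid
#' edge effects. The volume's `offset` is updated so window-center
#' coordinates stay expressed in the original acquisition frame.
#'
#' @param volume A `multiplex_volume`.
#' @param n_pixels Border width, with `2 * n_pixels` smaller than both
#'   lateral dims.
#' @return The trimmed `multiplex_volume`.
#' @export
trim_border <- function(volume, n_pixels) {
  n <- as.integer(n_pixels)
  if (n < 0L) stopf("`n_pixels` must be >= 0")
  if (n == 0L) return(volume)
  d <- vol_dims(volume)
  if (2L * n >= d[2] || 2L * n >= d[3]) {
    stopf("border %d too large for lateral dims %d x %d", n, d[2], d[3])
  }
  ys <- (n + 1L):(d[2] - n)
  xs <- (n + 1L):(d[3] - n)
  volume$stacks <- lapply(volume$stacks, function(s) {
    channel_stack(s$channel, s$marker, s$data[, ys, xs, drop = FALSE])
  })
  volume$offset <- volume$offset + c(0L, n, n)
  volume
}

#' Nucleus mask from the phosphorus channel
#'
#' Otsu threshold on the plane-summed phosphorus image, morphological
#' closing, hole filling, and removal of small components. Phosphorus
#' tracks DNA, so the surviving components are the nuclei.
#'
#' @param phosphorus_stack The `"31P"` [channel_stack()] or 3D array.
#' @param z_range Planes to sum (default: all).
#' @param closing_radius Disc radius (px) for morphological closing.
#' @param min_area Minimum component area (px) to keep.
#' @return Logical `[y, x]` mask.
#' @export
nucleus_mask <- function(phosphorus_stack, z_range = NULL, closing_radius = 3,
                         min_area = 100) {
  img <- sum_planes(phosphorus_stack, z_range)
  if (all(img == 0)) stopf("phosphorus channel is empty")
  if (diff(range(img)) == 0) return(matrix(TRUE, nrow(img), ncol(img)))
  scaled <- (img - min(img)) / diff(range(img))
  # EBImage works in (x, y); transpose in and out
  ei <- EBImage::Image(t(scaled))
  thr <- EBImage::otsu(ei, range = c(0, 1))
  bw <- ei > thr
  brush <- EBImage::makeBrush(2 * closing_radius + 1, shape = "disc")
  bw <- EBImage::closing(bw, brush)
  bw <- EBImage::fillHull(bw)
  lab <- EBImage::bwlabel(bw)
  areas <- table(lab[lab > 0])
  keep <- as.integer(names(areas)[areas >= min_area])
  mask <- matrix(as.numeric(lab) %in% keep, nrow(lab), ncol(lab))
  t(mask)
}
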