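# Voxel feature extraction and normalization. A "voxel" here is a 3D
# sliding window summarized by the per-channel mean ion count; tables carry
# window/step provenance and window-center coordinates in original-frame
# pixels so that interaction radii stay in instrument units.

# Column-wise cumulative sum along one axis of a 3D array.
cumsum_axis <- function(arr, axis) {
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  m <- matrix(a, nrow = d[axis])
  cm <- matrix(cumsum(m), nrow = d[axis])
  if (ncol(m) > 1L) {
    base <- c(0, cm[d[axis], -ncol(m)])
    cm <- cm - rep(base, each = d[axis])
  }
  aperm(array(cm, dim = d[perm]), order(perm))
}

#' Extract sliding-window voxel features
#'
#' Applies a 3D sliding window to every channel and emits one row per fully
#' contained window with the per-channel arithmetic mean of the counts in
#' that window. Partial windows at the edges are dropped. Centers are the
#' geometric window centers in 0-based original-frame pixel coordinates
#' (border trimming and z-restriction are accounted for via the volume
#' offset).
#'
#' @param volume A `multiplex_volume`.
#' @param window Window size `(wx, wy, wz)` in pixels.
#' @param step Step size `(sx, sy, sz)`, all >= 1.
#' @param z_range Optional 1-based plane range to restrict to (e.g. from
#'   [middle_z_range()]).
#' @param border Lateral border width to trim first (see [trim_border()]).
#' @param channels Channels to extract (default: all).
#' @return A data.frame with columns `fov_id, x, y, z` and one column per
#'   channel, plus `window`/`step`/`channels` attributes.
#' @export
sliding_window_features <- function(volume, window, step = window,
                                    z_range = NULL, border = 0,
                                    channels = vol_channels(volume)) {
  if (border > 0) volume <- trim_border(volume, border)
  d <- vol_dims(volume)
  off <- volume$offset
  if (!is.null(z_range)) {
    if (any(z_range < 1L | z_range > d[1])) stopf("z_range outside depth %d", d[1])
    volume$stacks <- lapply(volume$stacks, function(s) {
      channel_stack(s$channel, s$marker, s$data[z_range, , , drop = FALSE])
    })
    off[1] <- off[1] + z_range[1] - 1L
    d <- vol_dims(volume)
  }
  w <- as.integer(window); s <- as.integer(step)
  if (length(w) != 3L || length(s) != 3L) stopf("`window` and `step` must be length 3")
  if (any(s < 1L)) stopf("steps must be >= 1")
  wzyx <- rev(w); szyx <- rev(s)           # internal arrays are (z, y, x)
  if (any(wzyx > d)) {
    stopf("window (%s) larger than region (%s)",
          paste(w, collapse = ","), paste(rev(d), collapse = ","))
  }
  starts <- lapply(1:3, function(a) seq(1L, d[a] - wzyx[a] + 1L, by = szyx[a]))
  g <- expand.grid(z0 = starts[[1]], y0 = starts[[2]], x0 = starts[[3]],
                   KEEP.OUT.ATTRS = FALSE)

  pd <- d + 1L
  corner_idx <- function(az, ay, ax) az + (ay - 1L) * pd[1] + (ax - 1L) * pd[1] * pd[2]
  z0 <- g$z0; y0 <- g$y0; x0 <- g$x0
  z1 <- z0 + wzyx[1]; y1 <- y0 + wzyx[2]; x1 <- x0 + wzyx[3]  # hi corner + 1
  nvox <- prod(wzyx)

  feats <- matrix(0, nrow = nrow(g), ncol = length(channels),
                  dimnames = list(NULL, channels))
  for (ch in channels) {
    P <- array(0, dim = pd)
    cs <- cumsum_axis(cumsum_axis(cumsum_axis(volume$stacks[[ch]]$data, 1), 2), 3)
    P[-1, -1, -1] <- cs
    Pv <- as.vector(P)
    sums <- Pv[corner_idx(z1, y1, x1)] - Pv[corner_idx(z0, y1, x1)] -
      Pv[corner_idx(z1, y0, x1)] - Pv[corner_idx(z1, y1, x0)] +
      Pv[corner_idx(z0, y0, x1)] + Pv[corner_idx(z0, y1, x0)] +
      Pv[corner_idx(z1, y0, x0)] - Pv[corner_idx(z0, y0, x0)]
    feats[, ch] <- sums / nvox
  }

  tab <- data.frame(
    fov_id = volume$fov_id,
    x = off[3] + (x0 - 1L) + (w[1] - 1) / 2,
    y = off[2] + (y0 - 1L) + (w[2] - 1) / 2,
    z = off[1] + (z0 - 1L) + (w[3] - 1) / 2,
    check.names = FALSE, stringsAsFactors = FALSE
  )
  tab <- cbind(tab, as.data.frame(feats, check.names = FALSE))
  attr(tab, "window") <- w
  attr(tab, "step") <- s
  attr(tab, "channels") <- channels
  attr(tab, "normalization") <- "none"
  tab
}

#' Channel columns of a voxel table
#' @param table A voxel table.
#' @export
voxel_channels <- function(table) {
  attr(table, "channels") %||%
    setdiff(names(table), c(required_voxel_cols, "neighborhood", "condition"))
}

keep_attrs <- function(out, table, normalization = NULL) {
  for (key in c("window", "step", "channels")) attr(out, key) <- attr(table, key)
  norm <- attr(table, "normalization") %||% "none"
  if (!is.null(normalization)) {
    norm <- if (identical(norm, "none")) normalization else paste(norm, normalization, sep = "+")
  }
  attr(out, "normalization") <- norm
  out
}

#' Centered z-slab helper
#'
#' The middle `n_planes` planes of a stack of depth `nz`; for odd
#' remainders the extra plane is left on the leading (shallow) side.
#'
#' @param nz Stack depth.
#' @param n_planes Slab thickness (default 40).
#' @return Integer vector of 1-based plane indices.
#' @export
middle_z_range <- function(nz, n_planes = 40) {
  if (n_planes > nz) stopf("slab of %d planes exceeds depth %d", n_planes, nz)
  start <- floor((nz - n_planes) / 2) + 1L
  seq.int(start, start + n_planes - 1L)
}

#' Keep voxels whose lateral center falls on a mask
#'
#' @param table A voxel table (original-frame coordinates).
#' @param mask2d Logical `[y, x]` mask in the original frame.
#' @return The filtered table (possibly empty).
#' @export
mask_filter <- function(table, mask2d) {
  iy <- floor(table$y) + 1L
  ix <- floor(table$x) + 1L
  if (any(iy < 1L | iy > nrow(mask2d) | ix < 1L | ix > ncol(mask2d))) {
    stopf("voxel centers fall outside the mask frame")
  }
  keep <- mask2d[cbind(iy, ix)]
  keep_attrs(table[keep, , drop = FALSE], table)
}

#' Random voxel sampling without replacement
#'
#' @param table A voxel table.
#' @param n Rows to draw per group (or overall if `per_group` is `NULL`).
#' @param seed Integer seed; the sample is deterministic given the seed.
#' @param per_group Optional grouping column (e.g. `"fov_id"`).
#' @return The sampled table, in original row order.
#' @export
sample_voxels <- function(table, n, seed = 1L, per_group = NULL) {
  idx_groups <- if (is.null(per_group)) list(seq_len(nrow(table)))
  else split(seq_len(nrow(table)), table[[per_group]])
  small <- vapply(idx_groups, length, integer(1)) < n
  if (any(small)) {
    stopf("group '%s' has fewer than n = %d rows",
          names(idx_groups)[small][1] %||% "all", n)
  }
  take <- with_seed(seed, {
    unlist(lapply(idx_groups, function(ix) sort(sample(ix, n))), use.names = FALSE)
  })
  keep_attrs(table[sort(take), , drop = FALSE], table)
}

#' Drop voxels with low organic (carbon) signal
#'
#' Removes, per group, the `floor(fraction * n)` rows with the smallest
#' values of the carbon channel (ties broken by stable row order), to
#' discard voxels not associated with organic material.
#'
#' @param table A voxel table.
#' @param channel Carbon channel name (default `"12C"`).
#' @param fraction Fraction to remove (default 0.2).
#' @param per_group Grouping column (default `"fov_id"`).
#' @return The filtered table.
#' @export
filter_low_carbon <- function(table, channel = "12C", fraction = 0.2,
                              per_group = "fov_id") {
  if (!channel %in% names(table)) stopf("channel '%s' missing from table", channel)
  if (fraction <= 0) return(table)
  idx_groups <- if (is.null(per_group)) list(seq_len(nrow(table)))
  else split(seq_len(nrow(table)), table[[per_group]])
  drop <- unlist(lapply(idx_groups, function(ix) {
    k <- floor(fraction * length(ix))
    if (k == 0L) return(integer(0))
    ix[order(table[[channel]][ix])[seq_len(k)]]  # order() is stable
  }), use.names = FALSE)
  keep <- setdiff(seq_len(nrow(table)), drop)
  keep_attrs(table[keep, , drop = FALSE], table)
}

normalize_channels <- function(table, channels, fun, tag) {
  for (ch in channels) {
    if (!ch %in% names(table)) stopf("channel '%s' missing from table", ch)
    table[[ch]] <- fun(table[[ch]], ch)
  }
  keep_attrs(table, table, normalization = tag)
}

#' Z-score normalization (population SD)
#'
#' `(x - mean) / sd` per channel over all rows, with the population
#' (divide-by-n) standard deviation. Constant channels map to all zeros
#' with a warning.
#'
#' @param table A voxel table.
#' @param channels Channels to normalize (default: all).
#' @export
zscore <- function(table, channels = voxel_channels(table)) {
  normalize_channels(table, channels, function(x, ch) {
    s <- sqrt(mean((x - mean(x))^2))
    if (s == 0) {
      warning(sprintf("channel '%s' is constant; z-scores set to 0", ch))
      return(rep(0, length(x)))
    }
    (x - mean(x)) / s
  }, "zscore")
}

#' Min-max normalization to [0, 1]
#' @inheritParams zscore
#' @export
minmax <- function(table, channels = voxel_channels(table)) {
  normalize_channels(table, channels, function(x, ch) {
    r <- range(x)
    if (diff(r) == 0) {
      warning(sprintf("channel '%s' is constant; min-max set to 0", ch))
      return(rep(0, length(x)))
    }
    (x - r[1]) / diff(r)
  }, "minmax")
}

#' Log2 transform with pseudocount
#'
#' `x -> log2(x + pc)`; the default pseudocount 1e-4 avoids zeros while
#' leaving counts >= 1 nearly unchanged.
#'
#' @inheritParams zscore
#' @param pc Pseudocount (default `1e-4`).
#' @export
log2_pseudocount <- function(table, channels = voxel_channels(table), pc = 1e-4) {
  normalize_channels(table, channels, function(x, ch) log2(x + pc),
                     sprintf("log2+%g", pc))
}

#' Percentile normalization (mean-scaled, lo-hi percentile to [0, 1])
#'
#' Per group and channel: scales so the channel mean is 1, then maps the
#' `lo`-th percentile to 0 and the `hi`-th to 1 linearly, clipping outside
#' `[0, 1]`. Percentiles use linear interpolation between order statistics
#' (R's default `type = 7`). The mean scaling does not change the result
#' (the percentile map is invariant to positive scaling) but is kept so
#' intermediate values match the documented procedure.
#'
#' @param table A voxel table.
#' @param channels Channels to normalize.
#' @param lo,hi Percentiles in `[0, 100]`, `lo < hi`.
#' @param per_group Grouping column (default `"fov_id"`); `NULL` for global.
#' @export
percentile_normalize <- function(table, channels = voxel_channels(table),
                                 lo = 20, hi = 95, per_group = "fov_id") {
  if (lo >= hi) stopf("`lo` must be below `hi`")
  idx_groups <- if (is.null(per_group)) list(seq_len(nrow(table)))
  else split(seq_len(nrow(table)), table[[per_group]])
  for (ch in channels) {
    if (!ch %in% names(table)) stopf("channel '%s' missing from table", ch)
    for (ix in idx_groups) {
      x <- table[[ch]][ix]
      if (diff(range(x)) == 0) {
        warning(sprintf("channel '%s' is constant in a group; set to 0", ch))
        table[[ch]][ix] <- 0
        next
      }
      x <- x / mean(x)
      q <- stats::quantile(x, c(lo, hi) / 100, names = FALSE, type = 7)
      table[[ch]][ix] <- pmin(pmax((x - q[1]) / (q[2] - q[1]), 0), 1)
    }
  }
  keep_attrs(table, table, normalization = sprintf("pct%g-%g", lo, hi))
}

#' Global clip normalization
#'
#' `x -> clamp((x - lo) / (hi - lo), 0, 1)` applied globally (across all
#' FOVs), used for drug channels whose abundance differs between treated
#' and untreated cells and must not be rescaled per FOV.
#'
#' @param table A voxel table.
#' @param channel Channel to normalize.
#' @param lo,hi Global clip limits (defaults 0.01 and 0.05 mean counts).
#' @export
clip_normalize <- function(table, channel, lo = 0.01, hi = 0.05) {
  if (lo >= hi) stopf("`lo` must be below `hi`")
  normalize_channels(table, channel, function(x, ch) {
    pmin(pmax((x - lo) / (hi - lo), 0), 1)
  }, sprintf("clip%g-%g", lo, hi))
}
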