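# On-disk data model: one multi-page TIFF per isotope channel (pages = z,
# ascending acquisition depth), a YAML manifest naming channels/markers/files,
# and TSV tables for voxel features and results. Arrays are indexed [z, y, x]
# and coordinates are 0-based pixel units throughout.

#' Create a single-channel ion-count stack
#'
#' A channel stack holds the 3D ion-count grid acquired for one isotope
#' (e.g. `"19F"` carrying nucleolin signal), indexed `[z, y, x]`.
#'
#' @param channel Channel name, typically the isotope (e.g. `"31P"`).
#' @param marker Biological marker detected on this channel (e.g. `"DNA"`).
#' @param data 3D numeric array `[z, y, x]` of nonnegative finite counts.
#' @return An object of class `channel_stack`.
#' @export
channel_stack <- function(channel, marker, data) {
  if (!is.character(channel) || length(channel) != 1L || !nzchar(channel)) {
    stopf("`channel` must be a non-empty string")
  }
  if (length(dim(data)) != 3L) stopf("channel '%s': data must be a 3D array", channel)
  if (any(!is.finite(data))) stopf("channel '%s': non-finite values", channel)
  if (any(data < 0)) stopf("channel '%s': negative values", channel)
  structure(
    list(channel = channel, marker = as.character(marker), data = data),
    class = "channel_stack"
  )
}

#' Create a multiplexed volume from aligned channel stacks
#'
#' @param stacks List of [channel_stack()] objects sharing identical
#'   dimensions.
#' @param fov_id Field-of-view identifier.
#' @param offset Length-3 integer `(z, y, x)` origin of this (possibly
#'   cropped) volume in the original acquisition frame, 0-based. Border
#'   trimming updates it so voxel coordinates stay in the original frame.
#' @param pixel_size_nm Optional lateral pixel size in nm (metadata only).
#' @return An object of class `multiplex_volume`.
#' @export
multiplex_volume <- function(stacks, fov_id = "fov1", offset = c(0L, 0L, 0L),
                             pixel_size_nm = NULL) {
  if (length(stacks) == 0L) stopf("a volume needs at least one channel")
  if (!all(vapply(stacks, inherits, logical(1), "channel_stack"))) {
    stopf("`stacks` must be a list of channel_stack objects")
  }
  nms <- vapply(stacks, `[[`, character(1), "channel")
  if (anyDuplicated(nms)) stopf("duplicate channel names: %s",
                                paste(unique(nms[duplicated(nms)]), collapse = ", "))
  dims <- lapply(stacks, function(s) dim(s$data))
  if (!all(vapply(dims, identical, logical(1), dims[[1]]))) {
    stopf("channel stacks have mismatched dimensions")
  }
  names(stacks) <- nms
  structure(
    list(stacks = stacks, fov_id = fov_id, offset = as.integer(offset),
         pixel_size_nm = pixel_size_nm),
    class = "multiplex_volume"
  )
}

#' @export
print.multiplex_volume <- function(x, ...) {
  d <- vol_dims(x)
  cat(sprintf("multiplex_volume '%s': %d channel(s), dims (z,y,x) = %d x %d x %d\n",
              x$fov_id, length(x$stacks), d[1], d[2], d[3]))
  for (s in x$stacks) {
    cat(sprintf("  %-6s %-14s total counts %.4g\n", s$channel, s$marker, sum(s$data)))
  }
  invisible(x)
}

#' Volume dimensions
#' @param volume A `multiplex_volume`.
#' @return Integer `(n_z, n_y, n_x)`.
#' @export
vol_dims <- function(volume) dim(volume$stacks[[1]]$data)

#' Channel names of a volume
#' @param volume A `multiplex_volume`.
#' @export
vol_channels <- function(volume) names(volume$stacks)

# -- TIFF + manifest ---------------------------------------------------------

stack_to_pages <- function(data) {
  d <- dim(data)
  lapply(seq_len(d[1]), function(z) matrix(data[z, , ], d[2], d[3]))
}

pages_to_stack <- function(pages) {
  nz <- length(pages)
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  arr <- array(0, dim = c(nz, ny, nx))
  for (z in seq_len(nz)) arr[z, , ] <- pages[[z]]
  arr
}

#' Write a multiplexed volume to disk
#'
#' One lossless 16-bit multi-page TIFF per channel (pages in ascending z)
#' plus a YAML manifest `manifest.yaml` listing channel, marker, and file.
#'
#' @param volume A `multiplex_volume` with integer counts in `[0, 65535]`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest path.
#' @export
write_volume <- function(volume, dir) {
  if (!inherits(volume, "multiplex_volume")) stopf("`volume` must be a multiplex_volume")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- list()
  for (s in volume$stacks) {
    if (any(s$data != round(s$data))) {
      stopf("channel '%s': TIFF output requires integer counts", s$channel)
    }
    if (max(s$data) > 65535) stopf("channel '%s': counts exceed 16-bit range", s$channel)
    file <- sprintf("%s.tif", gsub("[^A-Za-z0-9_.-]", "_", s$channel))
    pages <- lapply(stack_to_pages(s$data), function(m) m / 65535)
    tiff::writeTIFF(pages, file.path(dir, file), bits.per.sample = 16,
                    compression = "none")
    entries[[length(entries) + 1L]] <-
      list(channel = s$channel, marker = s$marker, file = file)
  }
  manifest <- list(fov_id = volume$fov_id, offset = as.integer(volume$offset),
                   channels = entries)
  if (!is.null(volume$pixel_size_nm)) manifest$pixel_size_nm <- volume$pixel_size_nm
  path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, path)
  invisible(path)
}

#' Read a multiplexed volume written by [write_volume()]
#'
#' Channels are returned in manifest order, never reordered. Dimensions are
#' validated across channels and negative values rejected.
#'
#' @param dir Directory containing `manifest.yaml` and the channel TIFFs,
#'   or the path of the manifest itself.
#' @return A `multiplex_volume`.
#' @export
read_volume <- function(dir) {
  manifest_path <- if (dir.exists(dir)) file.path(dir, "manifest.yaml") else dir
  if (!file.exists(manifest_path)) stopf("manifest not found: %s", manifest_path)
  manifest <- yaml::read_yaml(manifest_path)
  base <- dirname(manifest_path)
  stacks <- lapply(manifest$channels, function(e) {
    f <- file.path(base, e$file)
    if (!file.exists(f)) stopf("channel '%s': file missing (%s)", e$channel, e$file)
    pages <- tiff::readTIFF(f, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    channel_stack(e$channel, e$marker %||% "", pages_to_stack(pages))
  })
  dims <- lapply(stacks, function(s) dim(s$data))
  for (i in seq_along(dims)) {
    if (!identical(dims[[i]], dims[[1]])) {
      stopf("channel '%s' has dims %s but '%s' has %s",
            stacks[[i]]$channel, paste(dims[[i]], collapse = "x"),
            stacks[[1]]$channel, paste(dims[[1]], collapse = "x"))
    }
  }
  multiplex_volume(stacks, fov_id = manifest$fov_id %||% "fov1",
                   offset = as.integer(manifest$offset %||% c(0L, 0L, 0L)),
                   pixel_size_nm = manifest$pixel_size_nm)
}

#' Write an integer label volume (ground truth or neighborhood map) as TIFF
#'
#' @param labels 3D integer array `[z, y, x]`, values in `[0, 65535]`.
#' @param path Output TIFF path.
#' @export
write_label_volume <- function(labels, path) {
  if (length(dim(labels)) != 3L) stopf("`labels` must be a 3D array")
  pages <- lapply(stack_to_pages(labels), function(m) m / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none")
  invisible(path)
}

#' Read an integer label volume written by [write_label_volume()]
#' @param path TIFF path.
#' @export
read_label_volume <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- pages_to_stack(pages)
  storage.mode(arr) <- "integer"
  arr
}

# -- voxel tables ------------------------------------------------------------

required_voxel_cols <- c("fov_id", "x", "y", "z")

#' Write a voxel feature table as TSV
#'
#' Columns: `fov_id, x, y, z` (window centers, original-frame pixels), one
#' column per channel, plus any extra columns. Window/step/normalization
#' provenance is stored in `#key: value` comment lines before the header;
#' numeric values are written with 6 significant digits.
#'
#' @param table A voxel table (see [sliding_window_features()]).
#' @param path Output TSV path.
#' @export
write_voxel_table <- function(table, path) {
  miss <- setdiff(required_voxel_cols, names(table))
  if (length(miss)) stopf("voxel table lacks required columns: %s",
                          paste(miss, collapse = ", "))
  con <- file(path, "w")
  on.exit(close(con))
  for (key in c("window", "step", "normalization", "channels")) {
    val <- attr(table, key)
    if (!is.null(val)) {
      writeLines(sprintf("#%s: %s", key, paste(val, collapse = ",")), con)
    }
  }
  out <- table
  num <- vapply(out, is.numeric, logical(1)) & !vapply(out, is.integer, logical(1))
  out[num] <- lapply(out[num], signif, digits = 6)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a voxel feature table written by [write_voxel_table()]
#'
#' @param path TSV path.
#' @return A data.frame with provenance attributes restored; malformed rows
#'   raise an error naming the offending line.
#' @export
read_voxel_table <- function(path) {
  lines <- readLines(path)
  meta_idx <- grep("^#", lines)
  meta <- list()
  for (l in lines[meta_idx]) {
    m <- regmatches(l, regexec("^#([^:]+): ?(.*)$", l))[[1]]
    if (length(m) == 3L) meta[[m[2]]] <- strsplit(m[3], ",", fixed = TRUE)[[1]]
  }
  body <- lines[setdiff(seq_along(lines), meta_idx)]
  if (length(body) < 1L) stopf("no header line in %s", path)
  header <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  nfield <- lengths(strsplit(body, "\t", fixed = TRUE))
  if (length(body) > 1L) {
    bad <- which(nfield[-1] != length(header))
    if (length(bad)) {
      stopf("malformed row at line %d of %s (%d fields, expected %d)",
            bad[1] + 1L + length(meta_idx), path, nfield[bad[1] + 1L], length(header))
    }
  }
  tab <- utils::read.table(text = body, sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  miss <- setdiff(required_voxel_cols, names(tab))
  if (length(miss)) stopf("voxel table lacks required columns: %s",
                          paste(miss, collapse = ", "))
  for (key in c("window", "step")) {
    if (!is.null(meta[[key]])) attr(tab, key) <- as.numeric(meta[[key]])
  }
  if (!is.null(meta$normalization)) attr(tab, "normalization") <- meta$normalization
  if (!is.null(meta$channels)) attr(tab, "channels") <- meta$channels
  tab
}

# -- line scans --------------------------------------------------------------

#' Construct a line-scan profile
#'
#' @param position Strictly increasing sample coordinates (nm or px).
#' @param intensity Counts at each position.
#' @return A data.frame of class `linescan`.
#' @export
linescan <- function(position, intensity) {
  if (length(position) != length(intensity)) stopf("position/intensity length mismatch")
  if (any(diff(position) <= 0)) stopf("positions must be strictly increasing")
  structure(data.frame(position = position, intensity = intensity),
            class = c("linescan", "data.frame"))
}

#' Read/write a two-column line-scan TSV
#' @param path TSV path with columns `position`, `intensity`.
#' @export
read_linescan <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE)
  linescan(tab$position, tab$intensity)
}

#' @rdname read_linescan
#' @param scan A `linescan`.
#' @export
write_linescan <- function(scan, path) {
  utils::write.table(as.data.frame(scan), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
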