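# SIMS metrology utilities: knife-edge (84-16%) lateral resolution,
# current/yield tradeoff regression, axial sputter-rate estimation, and
# isotope barcode capacity.

#' 84-16% edge resolution from a line scan
#'
#' Normalizes the profile to its low/high plateaus (medians of the outer
#' `plateau_frac` of samples on each side), then returns the distance
#' between the positions where the normalized profile crosses 16% and 84%
#' of the plateau difference, by linear interpolation between samples.
#' For a Gaussian-blurred edge this distance equals `2 * sigma`. Invariant
#' to affine intensity transforms and to reversal of the scan direction.
#'
#' @param scan A [linescan()] (or data.frame with `position`, `intensity`).
#' @param plateau_frac Fraction of samples on each end used to estimate
#'   the plateaus (default 0.2).
#' @param smooth Optional odd moving-average width applied before
#'   interpolation (default 0, off).
#' @return Resolution in the scan's position units.
#' @export
edge_resolution_84_16 <- function(scan, plateau_frac = 0.2, smooth = 0) {
  x <- scan$position; y <- scan$intensity
  n <- length(x)
  if (n < 5L) stopf("line scan too short")
  if (smooth > 1) {
    k <- rep(1 / smooth, smooth)
    y <- as.numeric(stats::filter(y, k, sides = 2))
    keep <- !is.na(y)
    x <- x[keep]; y <- y[keep]; n <- length(x)
  }
  m <- max(2L, floor(plateau_frac * n))
  left <- stats::median(y[seq_len(m)])
  right <- stats::median(y[seq.int(n - m + 1L, n)])
  noise <- max(stats::mad(y[seq_len(m)]), stats::mad(y[seq.int(n - m + 1L, n)]))
  if (abs(right - left) <= 3 * noise || right == left) {
    stopf("no detectable transition (plateau difference within noise floor)")
  }
  yn <- (y - left) / (right - left)   # rises 0 -> 1 regardless of direction

  # locate the transition at the 50% crossing nearest the scan center,
  # then walk outward for the nearest 16% / 84% crossings
  cross <- function(level, from, dir) {
    i <- from
    while (i >= 1L && i < n) {
      lo <- yn[i]; hi <- yn[i + 1L]
      if ((lo - level) * (hi - level) <= 0 && lo != hi) {
        return(x[i] + (level - lo) / (hi - lo) * (x[i + 1L] - x[i]))
      }
      if (lo == level) return(x[i])
      i <- i + dir
    }
    NA_real_
  }
  half_idx <- which((yn[-n] - 0.5) * (yn[-1] - 0.5) <= 0)
  if (length(half_idx) == 0L) stopf("no detectable transition")
  mid <- half_idx[which.min(abs(half_idx - n / 2))]
  x16 <- cross(0.16, mid, -1L)
  if (is.na(x16)) x16 <- cross(0.16, mid, 1L)
  x84 <- cross(0.84, mid, 1L)
  if (is.na(x84)) x84 <- cross(0.84, mid, -1L)
  if (is.na(x16) || is.na(x84)) stopf("could not locate 16%%/84%% crossings")
  abs(x84 - x16)
}

#' Current/yield versus resolution tradeoff
#'
#' Ordinary least squares of total secondary-ion count against measured
#' resolution over acquisitions at different primary currents; reports the
#' fitted slope, intercept and R^2.
#'
#' @param points Data.frame with columns `resolution` and
#'   `total_ion_count` (a `current` column may be present, unused by the
#'   fit), >= 3 rows.
#' @return List `slope`, `intercept`, `r_squared`.
#' @export
yield_resolution_tradeoff <- function(points) {
  if (nrow(points) < 3L) stopf("need at least 3 points")
  if (stats::var(points$resolution) == 0) stopf("resolution has zero variance")
  fit <- stats::lm(total_ion_count ~ resolution, data = points)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = summary(fit)$r.squared)
}

#' Axial sputter rate
#'
#' Thickness eroded per acquisition plane: `known_thickness /
#' planes_to_erode`.
#'
#' @param known_thickness Sample thickness (e.g. nm), > 0.
#' @param planes_to_erode Number of planes needed to erode it, >= 1.
#' @return Thickness per plane, same units as `known_thickness`.
#' @export
sputter_rate <- function(known_thickness, planes_to_erode) {
  if (known_thickness <= 0) stopf("`known_thickness` must be > 0")
  if (planes_to_erode < 1) stopf("`planes_to_erode` must be >= 1")
  known_thickness / planes_to_erode
}

#' Breakthrough depth from a substrate/organic signal ratio profile
#'
#' Companion to [sputter_rate()]: given the per-depth ratio of substrate
#' signal (e.g. silicon) to organic signal, returns the first depth index
#' at which the ratio crosses half of its asymptotic (final-plateau) value
#' -- the plane at which the beam has eroded through the material.
#'
#' @param ratio_profile Numeric vector of per-depth ratios.
#' @param plateau_frac Fraction of trailing samples defining the asymptote
#'   (default 0.2).
#' @return Integer depth index.
#' @export
breakthrough_depth <- function(ratio_profile, plateau_frac = 0.2) {
  n <- length(ratio_profile)
  if (n < 3L) stopf("profile too short")
  m <- max(1L, floor(plateau_frac * n))
  asym <- stats::median(ratio_profile[seq.int(n - m + 1L, n)])
  if (asym <= 0) stopf("asymptote is not positive")
  idx <- which(ratio_profile >= asym / 2)
  if (length(idx) == 0L) stopf("profile never reaches half its asymptote")
  idx[1]
}

#' Isotope barcode capacity
#'
#' Number of distinguishable probe identities when each probe carries an
#' unordered combination of `labels_per_probe` distinct isotopes out of
#' `n_channels`: counted by exhaustive enumeration of the subsets and
#' cross-checked against `choose(n, k)`.
#'
#' @param n_channels Number of isotope channels, >= 1.
#' @param labels_per_probe Isotopes per probe, `1 <= k <= n_channels`.
#' @return Integer count.
#' @export
barcode_capacity <- function(n_channels, labels_per_probe) {
  n <- as.integer(n_channels); k <- as.integer(labels_per_probe)
  if (n < 1L) stopf("`n_channels` must be >= 1")
  if (k < 1L || k > n) stopf("`labels_per_probe` must be in [1, n_channels]")
  count <- ncol(utils::combn(n, k))
  stopifnot(count == choose(n, k))
  count
}
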