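# Synthetic phantom generation. The generators emulate the statistical
# structure of NanoSIMS acquisitions -- Poisson ion counts whose per-pixel
# mean depends on the subnuclear structure a pixel belongs to -- plus
# negative-binomial exon/intron count tables and blurred-edge line scans,
# each with recoverable ground truth.

# Higher-precedence structures overwrite lower ones where geometries overlap,
# mirroring the visual nesting of subnuclear domains (speckles sit inside
# euchromatin, the rim wraps the nucleolus, the lamina lines the envelope).
STRUCTURE_PRECEDENCE <- c(
  "speckle", "nucleolus", "perinucleolar_rim", "heterochromatin",
  "nucleus_envelope", "lamina", "euchromatin", "cytoplasm", "background"
)

#' Declare a phantom structure
#'
#' @param name One of `speckle`, `nucleolus`, `perinucleolar_rim`,
#'   `heterochromatin`, `nucleus_envelope`, `lamina`, `euchromatin`,
#'   `cytoplasm`, `background`.
#' @param geometry A list with `type` one of:
#'   * `"everywhere"` -- fills the whole grid (for background),
#'   * `"ellipsoid"` -- fields `center` `(z,y,x)` and `radii` `(rz,ry,rx)`,
#'   * `"shell"` -- ellipsoid shell; fields `center`, `radii` (outer) and
#'     `thickness` (px subtracted from each radius for the inner surface),
#'   * `"spheres"` -- fields `centers` (n x 3 matrix of `(z,y,x)`) and
#'     `radii` `(rz,ry,rx)` shared by all spheres.
#'   All coordinates are 0-based pixels.
#' @return A `structure_spec`.
#' @export
structure_spec <- function(name, geometry) {
  name <- match.arg(name, STRUCTURE_PRECEDENCE)
  if (is.null(geometry$type)) stopf("geometry needs a `type`")
  structure(list(name = name, geometry = geometry), class = "structure_spec")
}

#' Phantom configuration
#'
#' @param dims Grid size `(n_z, n_y, n_x)`, all >= 1.
#' @param structures List of [structure_spec()]; overlaps are resolved by the
#'   fixed precedence order (speckle first, background last).
#' @param intensity_matrix Numeric matrix of expected mean ion counts per
#'   pixel: one row per declared structure (rownames = structure names), one
#'   column per channel (colnames = channel names); all entries >= 0.
#' @param markers Optional named character vector mapping channel -> marker.
#' @param drug_channel Name of the drug channel (default `"194Pt"`).
#' @param seed Integer seed; the phantom is bit-reproducible given the seed.
#' @return A `phantom_config`.
#' @export
phantom_config <- function(dims, structures, intensity_matrix, markers = NULL,
                           drug_channel = "194Pt", seed = 1L) {
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(dims < 1L)) stopf("`dims` must be three integers >= 1")
  if (!all(vapply(structures, inherits, logical(1), "structure_spec"))) {
    stopf("`structures` must be a list of structure_spec objects")
  }
  snames <- vapply(structures, `[[`, character(1), "name")
  if (anyDuplicated(snames)) stopf("duplicate structure names")
  if (is.null(rownames(intensity_matrix)) || is.null(colnames(intensity_matrix))) {
    stopf("intensity_matrix needs structure rownames and channel colnames")
  }
  miss <- setdiff(snames, rownames(intensity_matrix))
  if (length(miss)) stopf("intensity_matrix lacks rows for: %s",
                          paste(miss, collapse = ", "))
  if (any(intensity_matrix < 0)) stopf("intensity_matrix entries must be >= 0")
  structure(
    list(dims = dims, structures = structures,
         intensity_matrix = intensity_matrix, markers = markers,
         drug_channel = drug_channel, seed = as.integer(seed)),
    class = "phantom_config"
  )
}

# Logical membership mask for one geometry on the (z,y,x) grid.
# zc/yc/xc are 0-based coordinate arrays of the full grid.
geometry_mask <- function(geom, dims, zc, yc, xc) {
  inside_grid <- function(center) {
    all(center >= 0) && all(center <= dims - 1L)
  }
  ellipsoid <- function(center, radii) {
    if (!inside_grid(center)) stopf("geometry center outside grid")
    if (any(radii <= 0)) stopf("ellipsoid radii must be positive")
    ((zc - center[1]) / radii[1])^2 + ((yc - center[2]) / radii[2])^2 +
      ((xc - center[3]) / radii[3])^2 <= 1
  }
  switch(geom$type,
    everywhere = array(TRUE, dim = dims),
    ellipsoid = ellipsoid(geom$center, geom$radii),
    shell = {
      inner <- geom$radii - geom$thickness
      if (any(inner <= 0)) stopf("shell thickness exceeds radii")
      ellipsoid(geom$center, geom$radii) & !ellipsoid(geom$center, inner)
    },
    spheres = {
      m <- array(FALSE, dim = dims)
      for (i in seq_len(nrow(geom$centers))) {
        m <- m | ellipsoid(geom$centers[i, ], geom$radii)
      }
      m
    },
    stopf("unknown geometry type '%s'", geom$type)
  )
}

#' Generate a synthetic nuclear phantom
#'
#' Paints the declared structures onto the grid in precedence order to
#' produce a ground-truth label volume, then draws each channel as
#' independent Poisson counts with per-pixel mean
#' `intensity_matrix[structure, channel]`.
#'
#' @param config A [phantom_config()].
#' @param fov_id Field-of-view id for the returned volume.
#' @return A list with `volume` (a `multiplex_volume`) and `truth` (a
#'   `ground_truth`: integer `label_volume` plus `structure_names`, the
#'   id -> name map).
#' @export
generate_nuclear_phantom <- function(config, fov_id = "fov1") {
  if (!inherits(config, "phantom_config")) stopf("`config` must be a phantom_config")
  dims <- config$dims
  zc <- array(rep(seq_len(dims[1]) - 1L, times = dims[2] * dims[3]), dim = dims)
  yc <- array(rep(rep(seq_len(dims[2]) - 1L, each = dims[1]), times = dims[3]),
              dim = dims)
  xc <- array(rep(seq_len(dims[3]) - 1L, each = dims[1] * dims[2]), dim = dims)

  snames <- vapply(config$structures, `[[`, character(1), "name")
  ord <- order(match(snames, STRUCTURE_PRECEDENCE), decreasing = TRUE)
  labels <- array(0L, dim = dims)
  for (i in ord) {  # lowest precedence painted first, overwritten by higher
    m <- geometry_mask(config$structures[[i]]$geometry, dims, zc, yc, xc)
    labels[m] <- i
  }
  if (any(labels == 0L)) {
    stopf("%d pixels unassigned; include a background structure", sum(labels == 0L))
  }

  channels <- colnames(config$intensity_matrix)
  stacks <- with_seed(config$seed, {
    lapply(channels, function(ch) {
      lambda <- config$intensity_matrix[snames[labels], ch]
      counts <- array(stats::rpois(length(lambda), lambda), dim = dims)
      marker <- if (!is.null(config$markers)) config$markers[[ch]] %||% ch else ch
      channel_stack(ch, marker, counts)
    })
  })
  truth <- structure(list(label_volume = labels, structure_names = snames),
                     class = "ground_truth")
  list(volume = multiplex_volume(stacks, fov_id = fov_id), truth = truth)
}

# -- default study phantom ---------------------------------------------------

#' Default channel/marker panel of the phantom
#'
#' Six isotope channels mirroring a typical subnuclear panel: carbon (organic
#' mass), nucleolin, DNA phosphorus, H3K9me3, H3K27Ac, cisplatin, SC35.
#' @export
default_markers <- function() {
  c("12C" = "carbon", "19F" = "nucleolin", "31P" = "DNA",
    "81Br" = "H3K9me3", "127I" = "H3K27Ac", "194Pt" = "cisplatin",
    "197Au" = "SC35")
}

#' Per-structure drug multipliers
#'
#' Encodes the speckle-enriched / heterochromatin-depleted partitioning of a
#' DNA-damaging drug as recoverable ground truth. `nuclear_excluded = TRUE`
#' returns the profile of a cell where the drug never reaches the nucleus
#' (multipliers near zero in all nuclear structures, cytoplasm unchanged).
#'
#' @param nuclear_excluded Logical.
#' @return Named numeric vector of multipliers on the base drug intensity.
#' @export
drug_multipliers <- function(nuclear_excluded = FALSE) {
  m <- c(speckle = 3, nucleolus = 1, perinucleolar_rim = 1,
         heterochromatin = 0.3, lamina = 0.5, euchromatin = 1.5,
         cytoplasm = 0.5, background = 0.02)
  if (nuclear_excluded) {
    nuclear <- c("speckle", "nucleolus", "perinucleolar_rim",
                 "heterochromatin", "lamina", "euchromatin")
    m[nuclear] <- 0.05
  }
  m
}

#' Build the default nuclear phantom configuration
#'
#' A single cell: cytoplasm ellipsoid containing a nucleus (euchromatin
#' ground state) with lamina shell, one nucleolus with perinucleolar rim,
#' and seeded speckle/heterochromatin blobs. Mean counts are modest (tens
#' per pixel), as in low-current iterative acquisitions.
#'
#' @param dims Grid `(n_z, n_y, n_x)`; default `c(20, 160, 160)`.
#' @param n_speckles,n_hetero Number of speckle / heterochromatin blobs.
#' @param drug_base Base mean count of the drug channel.
#' @param drug_mult Named per-structure multipliers, see [drug_multipliers()].
#' @param seed Integer seed (placement of blobs and Poisson noise).
#' @return A [phantom_config()].
#' @export
default_phantom_config <- function(dims = c(20, 160, 160), n_speckles = 6,
                                   n_hetero = 8,
                                   drug_base = 10,
                                   drug_mult = drug_multipliers(),
                                   seed = 1L) {
  dims <- as.integer(dims)
  ctr <- (dims - 1) / 2
  nuc_radii <- c(dims[1] * 0.45, dims[2] * 0.30, dims[3] * 0.30)
  cyto_radii <- c(dims[1] * 0.49, dims[2] * 0.46, dims[3] * 0.46)
  nucleolus_c <- ctr + c(0, -dims[2] * 0.08, dims[3] * 0.06)
  nucleolus_r <- c(dims[1] * 0.30, dims[2] * 0.09, dims[3] * 0.09)

  blob_centers <- with_seed(seed + 1L, {
    # rejection-sample blob centers inside the nucleus, away from the nucleolus
    draw <- function(n, min_dist_frac) {
      out <- matrix(0, 0, 3)
      while (nrow(out) < n) {
        p <- c(stats::runif(1, ctr[1] - nuc_radii[1] * 0.6, ctr[1] + nuc_radii[1] * 0.6),
               stats::runif(1, ctr[2] - nuc_radii[2] * 0.8, ctr[2] + nuc_radii[2] * 0.8),
               stats::runif(1, ctr[3] - nuc_radii[3] * 0.8, ctr[3] + nuc_radii[3] * 0.8))
        in_nuc <- sum(((p - ctr) / nuc_radii)^2) <= 0.8
        near_nucleolus <- sum(((p - nucleolus_c) / (nucleolus_r * 1.8))^2) <= 1
        if (in_nuc && !near_nucleolus) out <- rbind(out, p)
      }
      out
    }
    list(speckles = draw(n_speckles), hetero = draw(n_hetero))
  })
  blob_r <- c(max(2, dims[1] * 0.18), dims[2] * 0.045, dims[3] * 0.045)

  structures <- list(
    structure_spec("background", list(type = "everywhere")),
    structure_spec("cytoplasm", list(type = "ellipsoid", center = ctr,
                                     radii = cyto_radii)),
    structure_spec("euchromatin", list(type = "ellipsoid", center = ctr,
                                       radii = nuc_radii)),
    structure_spec("lamina", list(type = "shell", center = ctr, radii = nuc_radii,
                                  thickness = c(1, 3, 3))),
    structure_spec("nucleolus", list(type = "ellipsoid", center = nucleolus_c,
                                     radii = nucleolus_r)),
    structure_spec("perinucleolar_rim",
                   list(type = "shell", center = nucleolus_c,
                        radii = nucleolus_r * 1.35, thickness = nucleolus_r * 0.35)),
    structure_spec("speckle", list(type = "spheres",
                                   centers = blob_centers$speckles, radii = blob_r)),
    structure_spec("heterochromatin",
                   list(type = "spheres", centers = blob_centers$hetero,
                        radii = blob_r * 1.2))
  )

  channels <- names(default_markers())
  snames <- vapply(structures, `[[`, character(1), "name")
  im <- matrix(0, nrow = length(snames), ncol = length(channels),
               dimnames = list(snames, channels))
  # organic carbon everywhere inside the cell
  im[, "12C"] <- c(background = 2, cytoplasm = 25, euchromatin = 30, lamina = 30,
                   nucleolus = 35, perinucleolar_rim = 30, speckle = 30,
                   heterochromatin = 32)[snames]
  im[, "19F"] <- c(background = 0.2, cytoplasm = 1, euchromatin = 2, lamina = 2,
                   nucleolus = 30, perinucleolar_rim = 12, speckle = 2,
                   heterochromatin = 1)[snames]
  im[, "31P"] <- c(background = 0.5, cytoplasm = 3, euchromatin = 22, lamina = 28,
                   nucleolus = 12, perinucleolar_rim = 25, speckle = 15,
                   heterochromatin = 40)[snames]
  im[, "81Br"] <- c(background = 0.2, cytoplasm = 1, euchromatin = 3, lamina = 15,
                    nucleolus = 1, perinucleolar_rim = 12, speckle = 1,
                    heterochromatin = 30)[snames]
  im[, "127I"] <- c(background = 0.2, cytoplasm = 1, euchromatin = 20, lamina = 4,
                    nucleolus = 2, perinucleolar_rim = 5, speckle = 10,
                    heterochromatin = 1)[snames]
  im[, "197Au"] <- c(background = 0.2, cytoplasm = 1, euchromatin = 5, lamina = 1,
                     nucleolus = 1, perinucleolar_rim = 2, speckle = 40,
                     heterochromatin = 1)[snames]
  im[, "194Pt"] <- drug_base * drug_mult[snames]

  phantom_config(dims, structures, im, markers = default_markers(), seed = seed)
}

# -- edge line scan ----------------------------------------------------------

#' Generate a blurred-edge line scan
#'
#' A step of height `amplitude` at `x0 = 0`, convolved with a Gaussian of
#' width `sigma`, sampled every `step` units, with additive Gaussian noise.
#' The noiseless profile is `amplitude * pnorm(x / sigma)` (an ideal step
#' when `sigma = 0`), the standard edge-spread-function model used for
#' 84-16 resolution estimation.
#'
#' @param sigma Gaussian edge width (position units), >= 0.
#' @param step Sampling interval, > 0.
#' @param amplitude Step height (counts).
#' @param noise_sd Additive Gaussian noise SD (counts).
#' @param seed Integer seed.
#' @param half_width Half extent of the scan; defaults to
#'   `max(6 * sigma, 60 * step)` so both plateaus are well sampled.
#' @return A [linescan()].
#' @export
generate_edge_linescan <- function(sigma, step, amplitude, noise_sd = 0,
                                   seed = 1L, half_width = NULL) {
  if (step <= 0) stopf("`step` must be positive")
  if (sigma < 0) stopf("`sigma` must be >= 0")
  half_width <- half_width %||% max(6 * sigma, 60 * step)
  x <- seq(-half_width, half_width, by = step)
  y <- if (sigma == 0) amplitude * as.numeric(x >= 0) else
    amplitude * stats::pnorm(x / sigma)
  if (noise_sd > 0) y <- y + with_seed(seed, stats::rnorm(length(x), 0, noise_sd))
  linescan(x, y)
}

# -- splicing counts ---------------------------------------------------------

#' Generate synthetic exon/intron count tables
#'
#' Two conditions (`control`, `treatment`) with `n_replicates` each.
#' Per gene, a baseline exon/intron ratio is drawn log-normally around 4;
#' a random `frac_affected` of genes have their treatment ratio multiplied
#' by `effect_fold`. Counts are negative-binomial with mean set by the
#' gene's depth and ratio and gene-level dispersion `dispersion`
#' (`dispersion = 0` gives the Poisson limit, under which the exon count
#' conditional on the replicate total is exactly binomial -- the sampling
#' model the per-gene logistic test assumes).
#'
#' @param n_genes,n_replicates Counts.
#' @param frac_affected Fraction of genes with a ratio change, in `[0, 1]`.
#' @param effect_fold Multiplier on the treatment exon/intron ratio, > 0.
#' @param mean_depth Mean total (exon + intron) fragments per replicate, > 0.
#' @param dispersion NB dispersion (1/size); 0.05 is a typical cell-line
#'   value, 0 gives Poisson counts.
#' @param seed Integer seed.
#' @return A data.frame with columns `gene_id, condition, replicate,
#'   exon_count, intron_count, truth_affected`.
#' @export
generate_splicing_counts <- function(n_genes, n_replicates = 3,
                                     frac_affected = 0.1, effect_fold = 0.5,
                                     mean_depth = 500, dispersion = 0.05,
                                     seed = 1L) {
  if (frac_affected < 0 || frac_affected > 1) stopf("`frac_affected` must be in [0,1]")
  if (effect_fold <= 0) stopf("`effect_fold` must be > 0")
  if (mean_depth <= 0) stopf("`mean_depth` must be > 0")
  with_seed(seed, {
    gene_id <- sprintf("gene%05d", seq_len(n_genes))
    ratio <- exp(stats::rnorm(n_genes, log(4), 0.5))
    depth <- mean_depth * exp(stats::rnorm(n_genes, 0, 0.5))
    n_aff <- round(frac_affected * n_genes)
    affected <- logical(n_genes)
    affected[sample.int(n_genes, n_aff)] <- TRUE

    draw <- function(mu) {
      if (dispersion <= 0) stats::rpois(length(mu), mu)
      else stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion)
    }
    rows <- list()
    for (cond in c("control", "treatment")) {
      r <- if (cond == "treatment") ratio * ifelse(affected, effect_fold, 1) else ratio
      mu_ex <- depth * r / (1 + r)
      mu_in <- depth / (1 + r)
      for (rep_i in seq_len(n_replicates)) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = gene_id, condition = cond, replicate = rep_i,
          exon_count = draw(mu_ex), intron_count = draw(mu_in),
          truth_affected = affected, stringsAsFactors = FALSE
        )
      }
    }
    tab <- do.call(rbind, rows)
    rownames(tab) <- NULL
    tab
  })
}

#' Majority ground-truth label per voxel window
#'
#' Validation helper: for each voxel row, the most frequent ground-truth
#' structure id within the voxel's window footprint (ties broken by the
#' smaller id). Coordinates are mapped through the table's window
#' provenance, so it works on trimmed/z-restricted extractions.
#'
#' @param table Voxel table with original-frame centers and window attr.
#' @param label_volume Ground-truth integer label array `[z, y, x]`.
#' @return Integer vector of structure ids, aligned with the table rows.
#' @export
voxel_majority_labels <- function(table, label_volume) {
  w <- attr(table, "window") %||% c(1, 1, 1)
  half <- (w - 1) / 2
  d <- dim(label_volume)
  vapply(seq_len(nrow(table)), function(i) {
    xs <- (round(table$x[i] - half[1]) + 1L):(round(table$x[i] + half[1]) + 1L)
    ys <- (round(table$y[i] - half[2]) + 1L):(round(table$y[i] + half[2]) + 1L)
    zs <- (round(table$z[i] - half[3]) + 1L):(round(table$z[i] + half[3]) + 1L)
    if (min(xs) < 1L || min(ys) < 1L || min(zs) < 1L ||
        max(xs) > d[3] || max(ys) > d[2] || max(zs) > d[1]) {
      stopf("voxel footprint outside the label volume")
    }
    which.max(tabulate(label_volume[zs, ys, xs]))
  }, integer(1))
}

#' Five-structure region-of-interest phantom
#'
#' A region inside one nucleus: euchromatin ground state with four embedded
#' structure types (nucleolus, two speckles, two heterochromatin foci, two
#' lamina-associated domains), each column-shaped along z and carrying one
#' dominant marker channel, plus the speckle-enriched drug partitioning of
#' [drug_multipliers()]. Designed for parameter-recovery benchmarks of the
#' denoise/feature/cluster pipeline: structures are large relative to a
#' 10 px window so boundary-mixture voxels stay a small minority.
#'
#' @param dims Grid `(n_z, n_y, n_x)`; default `c(20, 500, 500)`.
#' @param drug_base Base mean count of the drug channel.
#' @param seed Integer seed.
#' @return A [phantom_config()] with 5 distinct structure classes.
#' @export
five_structure_phantom_config <- function(dims = c(20, 500, 500), seed = 1L,
                                          drug_base = 10) {
  dims <- as.integer(dims)
  ctr <- (dims - 1) / 2
  zr <- 1e6          # z-spanning columns
  blob <- function(o) t(vapply(o, function(v) ctr + c(0, v[1], v[2]), numeric(3)))
  structures <- list(
    structure_spec("euchromatin", list(type = "everywhere")),
    structure_spec("nucleolus", list(type = "ellipsoid",
                                     center = ctr + c(0, -50, 60),
                                     radii = c(zr, 44, 44))),
    structure_spec("speckle", list(type = "spheres",
                                   centers = blob(list(c(66, -66), c(-80, -36))),
                                   radii = c(zr, 38, 38))),
    structure_spec("heterochromatin",
                   list(type = "spheres",
                        centers = blob(list(c(66, 60), c(-26, -116))),
                        radii = c(zr, 39, 39))),
    structure_spec("lamina",
                   list(type = "spheres",
                        centers = blob(list(c(118, -20), c(-110, 60))),
                        radii = c(zr, 38, 38)))
  )
  channels <- names(default_markers())
  sn <- vapply(structures, `[[`, character(1), "name")
  im <- matrix(0, length(sn), length(channels), dimnames = list(sn, channels))
  im[, "12C"] <- c(euchromatin = 30, nucleolus = 35, speckle = 30,
                   heterochromatin = 32, lamina = 30)[sn]
  im[, "19F"] <- c(euchromatin = 2, nucleolus = 30, speckle = 2,
                   heterochromatin = 1, lamina = 1)[sn]
  im[, "31P"] <- c(euchromatin = 22, nucleolus = 12, speckle = 15,
                   heterochromatin = 40, lamina = 45)[sn]
  im[, "81Br"] <- c(euchromatin = 3, nucleolus = 1, speckle = 1,
                    heterochromatin = 30, lamina = 3)[sn]
  im[, "127I"] <- c(euchromatin = 20, nucleolus = 2, speckle = 10,
                    heterochromatin = 1, lamina = 2)[sn]
  im[, "197Au"] <- c(euchromatin = 5, nucleolus = 1, speckle = 40,
                     heterochromatin = 1, lamina = 1)[sn]
  im[, "194Pt"] <- drug_base * drug_multipliers()[sn]
  phantom_config(dims, structures, im, markers = default_markers(), seed = seed)
}
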