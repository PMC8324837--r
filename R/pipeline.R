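# Preset pipelines and the composite runner. Three published-style presets
# are encoded:
#  * "nuclear"   -- nucleus-masked 3x3x10 voxels, z-score normalization,
#                   feature-space clustering (drug kept out of clustering).
#  * "iterative" -- kNN density denoising, 100-px border trim, 10x10x5
#                   window with 5x5x3 step, log2(x + 1e-4), feature-space
#                   clustering including the drug channel.
#  * "multidrug" -- 12-px border, 3x3x7 window with 2x2x5 step over the
#                   middle 40 planes, per-FOV 20-95 percentile
#                   normalization (drug clip-normalized globally instead),
#                   bottom-20% carbon filter, t-SNE embedding clustered to
#                   40 then merged; carbon and drug excluded from
#                   clustering.

#' Preset pipeline parameters
#'
#' @param name `"nuclear"`, `"iterative"`, or `"multidrug"`.
#' @return Named list of stage parameters; any entry can be overridden by
#'   the caller before running.
#' @export
preset_config <- function(name = c("nuclear", "iterative", "multidrug")) {
  name <- match.arg(name)
  base <- list(
    preset = name, drug_channel = "194Pt", carbon_channel = "12C",
    denoise = FALSE, knn_k = 25, border = 0, middle_z = NULL,
    nucleus_mask = FALSE, carbon_filter = FALSE,
    n_sample = NULL, cluster_on = "features",
    perplexity = 30, k_initial = NULL, k_final = NULL
  )
  over <- switch(name,
    nuclear = list(
      window = c(3, 3, 10), step = c(3, 3, 10), middle_z = 40,
      nucleus_mask = TRUE, normalization = "zscore", n_sample = 20000,
      cluster_channels = c("197Au", "81Br", "31P", "19F", "127I"),
      k_initial = 10, k_final = 10
    ),
    iterative = list(
      window = c(10, 10, 5), step = c(5, 5, 3), border = 100, denoise = TRUE,
      normalization = "log2", log2_pc = 1e-4, n_sample = 20000,
      cluster_channels = c("197Au", "81Br", "31P", "19F", "127I", "194Pt"),
      k_initial = 20, k_final = 11
    ),
    multidrug = list(
      window = c(3, 3, 7), step = c(2, 2, 5), border = 12, middle_z = 40,
      normalization = "percentile", pct_lo = 20, pct_hi = 95,
      clip_lo = 0.01, clip_hi = 0.05, carbon_filter = TRUE,
      carbon_fraction = 0.2, n_sample = 5000,
      cluster_on = "embedding", k_initial = 40, k_final = 7,
      cluster_channels = NULL  # all channels except carbon and drug
    )
  )
  utils::modifyList(base, over)
}

#' Extract and normalize voxels from one volume under a preset
#'
#' Runs the preset's preprocessing (denoise, border trim, z-slab), the
#' sliding window, mask/carbon filters, per-FOV sampling, and the preset's
#' normalization. Raw (pre-normalization) channel values are kept in
#' columns suffixed `.raw` so downstream quantification can use counts.
#'
#' @param volume A `multiplex_volume`.
#' @param config From [preset_config()], possibly modified.
#' @param seed Integer seed for sampling.
#' @return A voxel table.
#' @export
extract_voxels <- function(volume, config, seed = 1L) {
  if (config$denoise) {
    volume <- denoise_volume(volume, k = config$knn_k,
                             cutoffs = config$knn_cutoffs %||% NULL)
  }
  z_range <- NULL
  if (!is.null(config$middle_z)) {
    z_range <- middle_z_range(vol_dims(volume)[1], config$middle_z)
  }
  mask <- NULL
  if (isTRUE(config$nucleus_mask)) {
    mask <- nucleus_mask(volume$stacks[["31P"]], z_range = z_range)
  }
  tab <- sliding_window_features(volume, window = config$window,
                                 step = config$step, z_range = z_range,
                                 border = config$border)
  if (!is.null(mask)) tab <- mask_filter(tab, mask)
  if (isTRUE(config$carbon_filter)) {
    tab <- filter_low_carbon(tab, channel = config$carbon_channel,
                             fraction = config$carbon_fraction %||% 0.2)
  }
  if (!is.null(config$n_sample) && nrow(tab) > config$n_sample) {
    tab <- sample_voxels(tab, config$n_sample, seed = seed)
  }
  ch <- voxel_channels(tab)
  raw <- tab[, ch, drop = FALSE]
  names(raw) <- paste0(ch, ".raw")
  tab <- switch(config$normalization,
    zscore = zscore(tab, ch),
    log2 = log2_pseudocount(tab, ch, pc = config$log2_pc %||% 1e-4),
    minmax = minmax(tab, ch),
    percentile = {
      nd <- setdiff(ch, config$drug_channel)
      out <- percentile_normalize(tab, nd, lo = config$pct_lo %||% 20,
                                  hi = config$pct_hi %||% 95)
      if (config$drug_channel %in% ch) {
        out <- clip_normalize(out, config$drug_channel,
                              lo = config$clip_lo %||% 0.01,
                              hi = config$clip_hi %||% 0.05)
      }
      out
    },
    none = tab,
    stopf("unknown normalization '%s'", config$normalization)
  )
  out <- cbind(tab, raw)
  keep_attrs(out, tab)
}

#' Identify neighborhoods from a (possibly multi-FOV) voxel table
#'
#' Clusters either the channel features directly (Ward/Euclidean) or a
#' Barnes-Hut t-SNE embedding of them, then merges the initial clusters to
#' `k_final` -- via a user-supplied merge map, or automatically from the
#' initial cluster profiles (see [merge_map_from_profiles()]).
#'
#' @param table A voxel table.
#' @param config From [preset_config()].
#' @param seed Integer seed (t-SNE).
#' @param merge_map Optional explicit initial -> final map; overrides the
#'   automatic profile-based merge.
#' @return A `neighborhood_model`: `labels`, `k_initial`, `k_final`,
#'   `merge_map`, `profiles` (final, mean), `embedding`, `channels_used`.
#' @export
identify_neighborhoods <- function(table, config, seed = 1L, merge_map = NULL) {
  ch <- config$cluster_channels %||%
    setdiff(voxel_channels(table), c(config$carbon_channel, config$drug_channel))
  ch <- intersect(ch, names(table))
  if (length(ch) == 0L) stopf("no clustering channels present in the table")
  feats <- as.matrix(table[, ch, drop = FALSE])
  embedding <- NULL
  k0 <- config$k_initial %||% stopf("k_initial not set")
  if (config$cluster_on == "embedding") {
    embedding <- embed_tsne(feats, perplexity = config$perplexity, seed = seed)
    labels0 <- cluster_on_embedding(embedding, k = k0)
  } else {
    labels0 <- hierarchical_cluster(feats, k = k0)
  }
  k_final <- config$k_final %||% k0
  if (is.null(merge_map)) {
    if (k_final < k0) {
      prof0 <- cluster_profile(table[, ch, drop = FALSE], labels0, stat = "mean")
      merge_map <- merge_map_from_profiles(prof0, k_final)
    } else {
      merge_map <- stats::setNames(seq_len(k0), seq_len(k0))
    }
  }
  labels <- merge_clusters(labels0, merge_map)
  structure(
    list(labels = labels, k_initial = k0, k_final = length(unique(labels)),
         merge_map = merge_map,
         profiles = cluster_profile(table[, ch, drop = FALSE], labels,
                                    stat = "mean"),
         embedding = embedding, channels_used = ch),
    class = "neighborhood_model"
  )
}

#' @export
print.neighborhood_model <- function(x, ...) {
  cat(sprintf("neighborhood_model: %d voxels, %d -> %d clusters, channels: %s\n",
              length(x$labels), x$k_initial, x$k_final,
              paste(x$channels_used, collapse = ", ")))
  print(round(x$profiles, 3))
  invisible(x)
}

# -- composite runner --------------------------------------------------------

log_line <- function(con, fmt, ...) {
  msg <- sprintf(fmt, ...)
  writeLines(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), msg), con)
  message(msg)
}

#' Simulate a phantom dataset onto disk
#'
#' @param config_path YAML config with fields `out_dir`, `seed`, and
#'   `simulate:` (`n_fovs`, `dims`, optional `drug_excluded` list of FOV
#'   indices whose phantom has the drug excluded from the nucleus).
#' @return Invisibly, the list of written manifest paths.
#' @export
simulate_dataset <- function(config_path) {
  cfg <- if (is.character(config_path)) yaml::read_yaml(config_path) else config_path
  sim <- cfg$simulate %||% stopf("config lacks a `simulate:` section")
  out_dir <- cfg$out_dir %||% stopf("config lacks `out_dir`")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(cfg$seed %||% 1L)
  n_fovs <- sim$n_fovs %||% 1L
  dims <- as.integer(sim$dims %||% c(20, 160, 160))
  excluded <- as.integer(sim$drug_excluded %||% integer(0))
  paths <- character(0)
  for (i in seq_len(n_fovs)) {
    mult <- drug_multipliers(nuclear_excluded = i %in% excluded)
    pc <- default_phantom_config(dims = dims, drug_mult = mult,
                                 drug_base = sim$drug_base %||% 10,
                                 seed = seed + i)
    ph <- generate_nuclear_phantom(pc, fov_id = sprintf("fov%02d", i))
    fov_dir <- file.path(out_dir, ph$volume$fov_id)
    paths <- c(paths, write_volume(ph$volume, fov_dir))
    write_label_volume(ph$truth$label_volume, file.path(fov_dir, "truth.tif"))
    yaml::write_yaml(as.list(ph$truth$structure_names),
                     file.path(fov_dir, "truth_structures.yaml"))
  }
  invisible(paths)
}

#' Run a preset pipeline end to end
#'
#' Reads volumes (or simulates them), extracts and normalizes voxels per
#' FOV, identifies neighborhoods on the pooled table, runs the interaction
#' permutation test, quantifies the drug channel per neighborhood, and
#' writes all tables plus a run log into `out_dir`.
#'
#' @param config_path Path to a YAML config (or an equivalent list):
#'   `preset`, `seed`, `out_dir`, either `inputs:` (list of volume dirs) or
#'   `simulate:`, optional `overrides:` of preset fields, optional
#'   `interactions: {radius, n_perm}`.
#' @return Invisibly, a list with `voxels`, `model`, `interaction`,
#'   `fractions`.
#' @export
run_pipeline <- function(config_path) {
  cfg <- if (is.character(config_path)) yaml::read_yaml(config_path) else config_path
  out_dir <- cfg$out_dir %||% stopf("config lacks `out_dir`")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(cfg$seed %||% 1L)
  config <- preset_config(cfg$preset %||% "iterative")
  if (!is.null(cfg$overrides)) config <- utils::modifyList(config, cfg$overrides)

  logf <- file(file.path(out_dir, "run.log"), "w")
  on.exit(close(logf))
  log_line(logf, "ionvox %s | preset %s | seed %d",
           as.character(utils::packageVersion("ionvox")), config$preset, seed)

  if (!is.null(cfg$simulate)) {
    sim_dir <- file.path(out_dir, "phantoms")
    simulate_dataset(list(out_dir = sim_dir, seed = seed, simulate = cfg$simulate))
    inputs <- list.dirs(sim_dir, recursive = FALSE)
  } else {
    inputs <- unlist(cfg$inputs) %||% stopf("config needs `inputs:` or `simulate:`")
    missing <- inputs[!file.exists(file.path(inputs, "manifest.yaml"))]
    if (length(missing)) stopf("missing input volume(s): %s",
                               paste(missing, collapse = ", "))
  }

  tabs <- list()
  for (i in seq_along(inputs)) {
    vol <- read_volume(inputs[[i]])
    tab <- extract_voxels(vol, config, seed = seed + i)
    log_line(logf, "%s: %d voxels after extraction", vol$fov_id, nrow(tab))
    tabs[[i]] <- tab
  }
  voxels <- do.call(rbind, tabs)
  voxels <- keep_attrs(voxels, tabs[[1]])
  log_line(logf, "pooled voxels: %d", nrow(voxels))
  write_voxel_table(voxels, file.path(out_dir, "voxels.tsv"))

  model <- identify_neighborhoods(voxels, config, seed = seed)
  log_line(logf, "neighborhoods: %d initial -> %d final",
           model$k_initial, model$k_final)
  utils::write.table(
    data.frame(voxels[required_voxel_cols], neighborhood = model$labels),
    file.path(out_dir, "labels.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(neighborhood = rownames(model$profiles), model$profiles,
               check.names = FALSE),
    file.path(out_dir, "profiles.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)

  icfg <- cfg$interactions %||% list()
  interaction <- permutation_test(as.matrix(voxels[, c("x", "y", "z")]),
                                  model$labels,
                                  radius = icfg$radius %||% 5,
                                  n_perm = icfg$n_perm %||% 1000,
                                  seed = seed)
  utils::write.table(interaction_table(interaction),
                     file.path(out_dir, "interactions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_interaction_graph(interaction, file.path(out_dir, "interactions.graphml"))

  fractions <- NULL
  drug_raw <- paste0(config$drug_channel, ".raw")
  drug_col <- if (config$drug_channel %in% names(voxels) &&
                  identical(config$normalization, "percentile")) {
    config$drug_channel       # clip-normalized: positive means above clip floor
  } else if (drug_raw %in% names(voxels)) drug_raw else NULL
  if (!is.null(drug_col)) {
    fractions <- positive_fraction(voxels, model$labels, drug_col)
    utils::write.table(fractions, file.path(out_dir, "positive_fractions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  log_line(logf, "done")
  invisible(list(voxels = voxels, model = model, interaction = interaction,
                 fractions = fractions))
}
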