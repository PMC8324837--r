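two_blobs <- function(n_per = 40, sep = 10, d = 3, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per * d), ncol = d),
             matrix(rnorm(n_per * d, mean = sep), ncol = d))
  list(x = x, truth = rep(1:2, each = n_per))
}

test_that("hierarchical clustering separates well-separated blobs", {
  b <- two_blobs()
  expect_equal(ari(hierarchical_cluster(b$x, k = 2), b$truth), 1)
  expect_true(all(hierarchical_cluster(b$x, k = 1) == 1))
  expect_equal(length(unique(hierarchical_cluster(b$x, k = nrow(b$x)))),
               nrow(b$x))
  expect_error(hierarchical_cluster(b$x, k = nrow(b$x) + 1), "outside")
  # deterministic for fixed input order
  expect_identical(hierarchical_cluster(b$x, k = 5),
                   hierarchical_cluster(b$x, k = 5))
})

test_that("t-SNE embedding is deterministic and separates blobs", {
  b <- two_blobs(n_per = 60, seed = 2)
  e1 <- embed_tsne(b$x, perplexity = 15, seed = 42, max_iter = 300)
  e2 <- embed_tsne(b$x, perplexity = 15, seed = 42, max_iter = 300)
  expect_identical(e1, e2)
  expect_identical(dim(e1), c(120L, 2L))

  inter <- sqrt(sum((colMeans(e1[b$truth == 1, ]) -
                       colMeans(e1[b$truth == 2, ]))^2))
  intra <- mean(c(dist(e1[b$truth == 1, ])))
  expect_gt(inter, intra)

  expect_error(embed_tsne(b$x, perplexity = 100), "perplexity")

  # clustering the embedding recovers the blobs (up to embedding stragglers)
  expect_gte(ari(cluster_on_embedding(e1, k = 2), b$truth), 0.8)
})

test_that("cluster merging follows the map and composes", {
  labels <- c(1L, 2L, 3L, 3L)
  expect_identical(merge_clusters(labels, c(`1` = 1, `2` = 1, `3` = 2)),
                   c(1L, 1L, 2L, 2L))
  expect_identical(merge_clusters(labels, c(`1` = 1, `2` = 2, `3` = 3)), labels)
  expect_true(all(merge_clusters(labels, c(`1` = 1, `2` = 1, `3` = 1)) == 1L))
  expect_error(merge_clusters(labels, c(`1` = 1)), "lacks entries")

  # merge twice with composed maps == single merge with the composition
  m1 <- c(`1` = 1, `2` = 1, `3` = 2)
  m2 <- c(`1` = 5, `2` = 5)
  composed <- c(`1` = 5, `2` = 5, `3` = 5)
  expect_identical(merge_clusters(merge_clusters(labels, m1), m2),
                   merge_clusters(labels, composed))
})

test_that("profile-based automatic merging groups similar clusters", {
  profiles <- rbind(c(10, 1, 1), c(9, 1.2, 0.8), c(1, 10, 1), c(1, 9, 1.4))
  rownames(profiles) <- 1:4
  map <- merge_map_from_profiles(profiles, 2)
  expect_equal(map[["1"]], map[["2"]])
  expect_equal(map[["3"]], map[["4"]])
  expect_false(map[["1"]] == map[["3"]])
})

test_that("cluster profiles report exact statistics", {
  tab <- data.frame(fov_id = "f", x = 1:6, y = 0, z = 0,
                    a = c(1, 1, 1, 5, 5, 5), b = c(2, 2, 2, 0, 0, 0))
  attr(tab, "channels") <- c("a", "b")
  labels <- rep(1:2, each = 3)
  prof <- cluster_profile(tab, labels, stat = "mean")
  expect_equal(unname(prof), rbind(c(1, 2), c(5, 0)))

  one <- cluster_profile(tab, rep(1L, 6), stat = "mean")
  expect_equal(as.numeric(one), unname(colMeans(tab[, c("a", "b")])))

  med <- cluster_profile(tab, labels, stat = "median")
  expect_equal(unname(med), rbind(c(1, 2), c(5, 0)))

  z <- cluster_profile(tab, labels, stat = "mean", row_normalize = "zscore")
  expect_equal(rowMeans(z), c(`1` = 0, `2` = 0))

  expect_error(cluster_profile(tab, labels[1:3]), "align")
})

test_that("size-weighted mean of z-scored features over clusters is zero", {
  set.seed(7)
  tab <- data.frame(fov_id = "f", x = 1:90, y = 0, z = 0,
                    a = rnorm(90, 5), b = rexp(90))
  attr(tab, "channels") <- c("a", "b")
  ztab <- zscore(tab)
  labels <- sample(1:3, 90, replace = TRUE, prob = c(0.6, 0.3, 0.1))
  prof <- cluster_profile(ztab, labels, stat = "mean")
  sizes <- as.numeric(table(labels))
  expect_equal(as.numeric(colSums(prof * sizes) / sum(sizes)), c(0, 0),
               tolerance = 1e-12)
})

test_that("polygon gating includes interior and boundary points", {
  square <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  pts <- rbind(c(0.5, 0.5), c(2, 2), c(1, 0.5), c(0, 0))
  expect_identical(gate_embedding(pts, square), c(TRUE, FALSE, TRUE, TRUE))

  # bounding rectangle of all points selects everything
  set.seed(30)
  coords <- matrix(rnorm(40), ncol = 2)
  bb <- rbind(c(min(coords[, 1]) - 1, min(coords[, 2]) - 1),
              c(max(coords[, 1]) + 1, min(coords[, 2]) - 1),
              c(max(coords[, 1]) + 1, max(coords[, 2]) + 1),
              c(min(coords[, 1]) - 1, max(coords[, 2]) + 1))
  expect_true(all(gate_embedding(coords, bb)))

  far <- rbind(c(100, 100), c(101, 100), c(100, 101))
  expect_false(any(gate_embedding(coords, far)))

  expect_error(gate_embedding(coords, rbind(c(0, 0), c(1, 1))), "3 vertices")
  expect_error(gate_embedding(coords, rbind(c(0, 0), c(0, 0), c(0, 0))),
               "degenerate")
})

test_that("neighborhood maps paint window footprints with their labels", {
  tab <- data.frame(fov_id = "f", x = 2, y = 3, z = 1)
  attr(tab, "window") <- c(3, 3, 3)
  m <- render_neighborhood_map(tab, 4L, frame_dims = c(3, 8, 8))
  expect_equal(sum(m == 4L), 9)
  expect_true(all(m[3:5, 2:4] == 4L))   # rows = y0..y1 + 1, cols = x0..x1 + 1

  # disjoint voxels never overwrite each other
  tab2 <- data.frame(fov_id = "f", x = c(1, 5), y = c(1, 5), z = c(1, 1))
  attr(tab2, "window") <- c(3, 3, 3)
  m2 <- render_neighborhood_map(tab2, c(1L, 2L), frame_dims = c(3, 8, 8))
  expect_equal(sum(m2 == 1L), 9)
  expect_equal(sum(m2 == 2L), 9)

  v <- render_neighborhood_map(tab2, c(1L, 2L), frame_dims = c(3, 8, 8),
                               mode = "volume")
  expect_equal(sum(v == 1L), 27)
  expect_equal(sum(v == 2L), 27)

  expect_error(render_neighborhood_map(tab2, c(1L, 2L), frame_dims = c(3, 4, 4)),
               "outside")
})

test_that("phantom voxels rendered by ground truth reproduce the label volume", {
  cfg <- default_phantom_config(dims = c(6, 40, 40), seed = 4)
  ph <- generate_nuclear_phantom(cfg)
  # single-pixel windows: majority label is the exact truth label, so the
  # rendered volume must reproduce the label volume on covered pixels
  tab <- sliding_window_features(ph$volume, window = c(1, 1, 1), step = c(2, 2, 2))
  maj <- voxel_majority_labels(tab, ph$truth$label_volume)
  vol <- render_neighborhood_map(tab, maj, frame_dims = vol_dims(ph$volume),
                                 mode = "volume")
  covered <- vol > 0
  expect_true(all((vol == ph$truth$label_volume)[covered]))
})
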