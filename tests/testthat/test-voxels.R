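vol_from_array <- function(arr, channel = "31P", fov = "fov1") {
  multiplex_volume(list(channel_stack(channel, channel, arr)), fov_id = fov)
}

test_that("sliding-window features equal brute-force window means", {
  # constant volume: every feature equals the constant
  const <- vol_from_array(array(7, c(6, 9, 9)))
  tab <- sliding_window_features(const, window = c(3, 3, 2), step = c(2, 2, 2))
  expect_true(all(tab[["31P"]] == 7))

  # window 1, step 1 reproduces raw pixel values
  set.seed(3)
  arr <- array(rpois(4 * 5 * 5, 6), c(4, 5, 5))
  raw <- sliding_window_features(vol_from_array(arr), window = c(1, 1, 1),
                                 step = c(1, 1, 1))
  expect_equal(nrow(raw), length(arr))
  expect_equal(raw[["31P"]][raw$x == 2 & raw$y == 3 & raw$z == 1], arr[2, 4, 3])

  # random instance against the direct-summation oracle
  arr2 <- array(rpois(10 * 24 * 24, 4), c(10, 24, 24))
  tab2 <- sliding_window_features(vol_from_array(arr2), window = c(10, 10, 5),
                                  step = c(5, 5, 3))
  expect_equal(nrow(tab2), 3 * 3 * 2)
  expect_equal(sort(unique(tab2$x)), c(4.5, 9.5, 14.5))
  expect_equal(sort(unique(tab2$z)), c(2, 5))
  oracle <- brute_window_means(arr2, window_zyx = c(5, 10, 10),
                               step_zyx = c(3, 5, 5))
  expect_equal(sort(tab2[["31P"]]), sort(oracle))
})

test_that("window counts follow floor((L - w)/s) + 1 on random geometries", {
  set.seed(99)
  for (rep in 1:25) {
    d <- c(sample(3:12, 1), sample(6:30, 1), sample(6:30, 1))
    w <- c(sample(seq_len(min(d[3], 6)), 1), sample(seq_len(min(d[2], 6)), 1),
           sample(seq_len(d[1]), 1))
    s <- c(sample(1:4, 1), sample(1:4, 1), sample(1:3, 1))
    vol <- vol_from_array(array(1, d))
    tab <- sliding_window_features(vol, window = w, step = s)
    expected <- prod(floor((c(d[3], d[2], d[1]) - w) / s) + 1)
    expect_equal(nrow(tab), expected)
  }
})

test_that("coordinates respect border trim and z restriction", {
  arr <- array(1, c(10, 30, 30))
  tab <- sliding_window_features(vol_from_array(arr), window = c(3, 3, 2),
                                 step = c(3, 3, 2), border = 6,
                                 z_range = 3:8)
  expect_true(all(tab$x >= 6 + 1))        # centers inside the trimmed region
  expect_true(all(tab$z >= 2))            # z offset from the slab start
  expect_true(all(tab$x <= 30 - 6))
  # window larger than the trimmed region errors
  expect_error(sliding_window_features(vol_from_array(arr),
                                       window = c(25, 25, 2), border = 6),
               "larger")
})

test_that("mask filtering keeps exactly the rows on true pixels", {
  arr <- array(1, c(4, 20, 20))
  tab <- sliding_window_features(vol_from_array(arr), window = c(2, 2, 2))
  all_true <- matrix(TRUE, 20, 20)
  expect_equal(nrow(mask_filter(tab, all_true)), nrow(tab))
  expect_equal(nrow(mask_filter(tab, !all_true)), 0)

  half <- matrix(FALSE, 20, 20); half[, 1:10] <- TRUE
  kept <- mask_filter(tab, half)
  expect_true(all(floor(kept$x) < 10))
  expect_equal(nrow(kept), sum(floor(tab$x) < 10))
})

test_that("voxel sampling is deterministic, per-group, and validates sizes", {
  arr <- array(1, c(4, 12, 12))
  a <- sliding_window_features(vol_from_array(arr, fov = "a"), window = c(2, 2, 2))
  b <- sliding_window_features(vol_from_array(arr, fov = "b"), window = c(2, 2, 2))
  tab <- rbind(a, b)
  attr(tab, "window") <- attr(a, "window")

  s1 <- sample_voxels(tab, 10, seed = 5, per_group = "fov_id")
  s2 <- sample_voxels(tab, 10, seed = 5, per_group = "fov_id")
  expect_identical(s1, s2)
  expect_equal(as.vector(table(s1$fov_id)), c(10, 10))

  full <- sample_voxels(a, nrow(a), seed = 1)
  expect_equal(full[order(full$x, full$y, full$z), ],
               a[order(a$x, a$y, a$z), ], ignore_attr = TRUE)
  expect_error(sample_voxels(a, nrow(a) + 1, seed = 1), "fewer")
})

test_that("carbon filtering drops the lowest quantile with stable ties", {
  tab <- data.frame(fov_id = "f", x = 0:9, y = 0, z = 0,
                    `12C` = c(5, 1, 9, 2, 8, 7, 6, 4, 3, 10),
                    check.names = FALSE)
  attr(tab, "channels") <- "12C"
  out <- filter_low_carbon(tab, fraction = 0.2)
  expect_equal(nrow(out), 8)
  expect_false(any(out[["12C"]] %in% c(1, 2)))

  expect_equal(nrow(filter_low_carbon(tab, fraction = 0)), 10)

  ties <- tab; ties[["12C"]] <- 5
  out2 <- filter_low_carbon(ties, fraction = 0.2)
  expect_equal(nrow(out2), 8)
  expect_equal(out2$x, 2:9)               # stable order drops the first rows
  expect_error(filter_low_carbon(tab, channel = "19F"), "19F")
})

test_that("z-score and min-max normalizations match closed forms", {
  tab <- data.frame(fov_id = "f", x = 1:3, y = 0, z = 0, ch = c(1, 2, 3))
  attr(tab, "channels") <- "ch"
  z <- zscore(tab)
  expect_equal(z$ch, c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  expect_equal(z$ch[3], 1.2247, tolerance = 1e-4)
  expect_equal(mean(z$ch), 0)
  expect_equal(sqrt(mean((z$ch - mean(z$ch))^2)), 1)

  mm <- tab; mm$ch <- c(2, 4, 6)
  attr(mm, "channels") <- "ch"
  expect_equal(minmax(mm)$ch, c(0, 0.5, 1))

  const <- tab; const$ch <- 5
  attr(const, "channels") <- "ch"
  expect_warning(zc <- zscore(const), "constant")
  expect_true(all(zc$ch == 0))
  expect_warning(mc <- minmax(const), "constant")
  expect_true(all(mc$ch == 0))
})

test_that("log2 pseudocount transform matches closed forms and is monotone", {
  tab <- data.frame(fov_id = "f", x = 1:3, y = 0, z = 0, ch = c(0, 1, 5))
  attr(tab, "channels") <- "ch"
  out <- log2_pseudocount(tab)
  expect_equal(out$ch[1], log2(1e-4))
  expect_equal(out$ch[1], -13.2877, tolerance = 1e-4)
  expect_equal(out$ch[2], log2(1.0001))
  expect_equal(out$ch[2], 0.000144, tolerance = 0.01)
  expect_true(all(diff(out$ch) > 0))
})

test_that("percentile normalization matches a brute-force percentile oracle", {
  tab <- data.frame(fov_id = "f", x = seq_len(100), y = 0, z = 0,
                    ch = as.numeric(1:100))
  attr(tab, "channels") <- "ch"
  out <- percentile_normalize(tab, "ch", lo = 20, hi = 95)

  # oracle with the same (type 7) percentile convention, on the mean-scaled
  # values
  xs <- (1:100) / mean(1:100)
  q <- quantile(xs, c(0.20, 0.95), names = FALSE, type = 7)
  oracle <- pmin(pmax((xs - q[1]) / (q[2] - q[1]), 0), 1)
  expect_equal(out$ch, oracle)
  expect_true(out$ch[58] > 0 && out$ch[58] < 1)   # mid-range value is interior

  # values at/below the 20th percentile map to 0; at/above the 95th to 1
  expect_true(all(out$ch[1:20] == 0))
  expect_true(all(out$ch[96:100] == 1))

  # mean scaling does not change the mapping (affine invariance)
  noscale <- tab
  q2 <- quantile(tab$ch, c(0.20, 0.95), names = FALSE, type = 7)
  direct <- pmin(pmax((tab$ch - q2[1]) / (q2[2] - q2[1]), 0), 1)
  expect_equal(out$ch, direct)

  expect_error(percentile_normalize(tab, "ch", lo = 95, hi = 20), "lo")
})

test_that("clip normalization maps the stated anchor points", {
  tab <- data.frame(fov_id = "f", x = 1:5, y = 0, z = 0,
                    pt = c(0, 0.01, 0.03, 0.05, 0.2))
  attr(tab, "channels") <- "pt"
  out <- clip_normalize(tab, "pt", lo = 0.01, hi = 0.05)
  expect_equal(out$pt, c(0, 0, 0.5, 1, 1))
})

test_that("normalizations are order-preserving and permutation-commuting", {
  set.seed(12)
  tab <- data.frame(fov_id = "f", x = 1:50, y = 0, z = 0,
                    ch = rexp(50) * 10)
  attr(tab, "channels") <- "ch"
  for (f in list(function(t) zscore(t), function(t) minmax(t),
                 function(t) log2_pseudocount(t),
                 function(t) percentile_normalize(t, "ch"))) {
    out <- f(tab)
    expect_true(all(diff(out$ch[order(tab$ch)]) >= 0))
    perm <- sample(50)
    ptab <- tab[perm, ]
    attr(ptab, "channels") <- "ch"
    expect_equal(f(ptab)$ch, out$ch[perm])
  }
})

test_that("middle z slab is centered with floor on the leading side", {
  expect_equal(middle_z_range(50, 40), 6:45)
  expect_equal(middle_z_range(41, 40), 1:40)
  expect_equal(middle_z_range(40, 40), 1:40)
  expect_error(middle_z_range(30, 40), "exceeds")
})
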