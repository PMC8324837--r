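test_that("pairwise distance is the 3D Euclidean norm", {
  expect_equal(pairwise_distance(c(0, 0, 0), c(3, 4, 0)), 5)
  expect_equal(pairwise_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(pairwise_distance(c(1, 1, 1), c(2, 2, 2)), sqrt(3))
})

test_that("interaction counting handles inclusion at the radius and diagonals", {
  # collinear voxels at x = 0, 3, 6; labels A, A, B; radius 5:
  # pair (1,2) dist 3 -> AA; pair (2,3) dist 3 -> AB; pair (1,3) dist 6 excluded
  coords <- cbind(x = c(0, 3, 6), y = 0, z = 0)
  M <- count_interactions(coords, c("A", "A", "B"), radius = 5)
  expect_equal(M["A", "A"], 1)
  expect_equal(M["A", "B"], 1)
  expect_equal(M["B", "A"], 1)
  expect_equal(M["B", "B"], 0)

  # distance exactly equal to the radius counts as interacting
  M2 <- count_interactions(cbind(c(0, 3), c(0, 4), c(0, 0)), c("A", "B"),
                           radius = 5)
  expect_equal(M2["A", "B"], 1)

  # mutually distant voxels: zero matrix
  far <- cbind(seq(0, 900, by = 100), 0, 0)
  expect_true(all(count_interactions(far, rep(c("A", "B"), 5), radius = 5) == 0))

  # n same-label voxels all within radius: diagonal = n(n-1)/2
  n <- 7
  tight <- matrix(runif(n * 3), ncol = 3)
  M3 <- count_interactions(tight, rep("A", n), radius = 5)
  expect_equal(M3["A", "A"], n * (n - 1) / 2)

  expect_error(count_interactions(far, c("A", "B")), "mismatch")
})

test_that("neighbor pairs equal a brute-force all-pairs scan", {
  set.seed(17)
  for (rep in 1:5) {
    n <- sample(20:120, 1)
    coords <- matrix(runif(n * 3, 0, 20), ncol = 3)
    r <- runif(1, 2, 6)
    pairs <- neighbor_pairs(coords, r)
    d <- as.matrix(dist(coords))
    brute <- which(upper.tri(d) & d <= r, arr.ind = TRUE)
    expect_equal(nrow(pairs), nrow(brute))
    key <- function(m) sort(paste(m[, 1], m[, 2]))
    expect_identical(key(pairs), key(brute))
  }
})

test_that("permutation test is bit-identical to the naive all-pairs oracle", {
  set.seed(23)
  n <- 150
  coords <- matrix(runif(n * 3, 0, 25), ncol = 3)
  labels <- sample(c("A", "B", "C"), n, replace = TRUE)
  fast <- permutation_test(coords, labels, radius = 5, n_perm = 100, seed = 9)
  slow <- naive_permutation_test(coords, labels, radius = 5, n_perm = 100,
                                 seed = 9)
  expect_identical(unname(fast$real_counts), slow$real_counts)
  expect_identical(unname(fast$perm_mean), slow$perm_mean)
  expect_identical(unname(fast$p_greater), slow$p_greater)
  expect_identical(unname(fast$p_less), slow$p_less)
  expect_identical(unname(fast$log2_enrichment), slow$log2_enrichment)
})

test_that("two tight distant blobs give extreme one-sided p-values", {
  blob <- function(center, n) sweep(matrix(runif(n * 3, -1, 1), ncol = 3), 2,
                                    center, `+`)
  set.seed(5)
  coords <- rbind(blob(c(0, 0, 0), 30), blob(c(100, 100, 100), 30))
  labels <- rep(c("A", "B"), each = 30)
  res <- permutation_test(coords, labels, radius = 5, n_perm = 400, seed = 2)

  pmin_att <- 1 / (400 + 1)
  expect_equal(res$p_greater["A", "A"], pmin_att)
  expect_equal(res$p_greater["B", "B"], pmin_att)
  expect_equal(res$p_less["A", "B"], pmin_att)
  expect_gt(res$log2_enrichment["A", "A"], 0)
  expect_true(is.nan(res$log2_enrichment["A", "B"]))  # zero observed AB pairs

  # enrichment is log2(real / perm_mean) wherever defined
  ok <- res$real_counts > 0 & res$perm_mean > 0
  expect_equal(res$log2_enrichment[ok],
               log2(res$real_counts[ok] / res$perm_mean[ok]))

  edges <- significant_edges(res, alpha = 0.05)
  expect_setequal(paste(edges$a, edges$b, edges$sign),
                  c("A A 1", "B B 1", "A B -1"))
  expect_equal(nrow(significant_edges(res, alpha = 0)), 0)
})

test_that("relabeling clusters permutes the result matrices consistently", {
  set.seed(31)
  coords <- matrix(runif(80 * 3, 0, 12), ncol = 3)
  labels <- sample(c("A", "B", "C"), 80, replace = TRUE)
  swapped <- c(A = "C", B = "B", C = "A")[labels]
  r1 <- permutation_test(coords, labels, radius = 4, n_perm = 50, seed = 3)
  r2 <- permutation_test(coords, swapped, radius = 4, n_perm = 50, seed = 3)
  perm <- c(3, 2, 1)  # level order A,B,C of r2 corresponds to C,B,A of r1
  expect_identical(unname(r2$real_counts), unname(r1$real_counts[perm, perm]))
  expect_identical(unname(r2$p_greater), unname(r1$p_greater[perm, perm]))
})

test_that("ordered-pair double counting would leave enrichment unchanged", {
  set.seed(41)
  coords <- matrix(runif(60 * 3, 0, 10), ncol = 3)
  labels <- sample(c("A", "B"), 60, replace = TRUE)
  res <- permutation_test(coords, labels, radius = 4, n_perm = 50, seed = 7)
  # doubling both observed and permuted counts cancels in the ratio
  ok <- res$real_counts > 0 & res$perm_mean > 0
  expect_equal(log2((2 * res$real_counts[ok]) / (2 * res$perm_mean[ok])),
               res$log2_enrichment[ok])
})

test_that("per-FOV testing shuffles within FOV and returns one result each", {
  set.seed(51)
  tab <- data.frame(fov_id = rep(c("f1", "f2"), each = 50),
                    x = runif(100, 0, 15), y = runif(100, 0, 15),
                    z = runif(100, 0, 5))
  labels <- sample(c("A", "B"), 100, replace = TRUE)
  res <- permutation_test_by_fov(tab, labels, radius = 5, n_perm = 30, seed = 1)
  expect_named(res, c("f1", "f2"))
  sub <- tab$fov_id == "f1"
  direct <- permutation_test(as.matrix(tab[sub, c("x", "y", "z")]),
                             factor(labels[sub], levels = c("A", "B")),
                             radius = 5, n_perm = 30, seed = 2)
  expect_identical(res$f1$real_counts, direct$real_counts)
  expect_identical(res$f1$p_greater, direct$p_greater)
})

test_that("interaction tables and graph export round out the results", {
  coords <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(50, 0, 0), c(51, 0, 0))
  labels <- c("A", "A", "B", "B", "B")
  res <- permutation_test(coords, labels, radius = 5, n_perm = 20, seed = 4)
  tab <- interaction_table(res)
  expect_equal(nrow(tab), 3)             # AA, AB, BB
  expect_equal(tab$real[tab$a == "A" & tab$b == "A"],
               res$real_counts["A", "A"])
  p <- withr::local_tempfile(fileext = ".graphml")
  write_interaction_graph(res, p)
  expect_true(file.exists(p) && file.size(p) > 0)
})
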