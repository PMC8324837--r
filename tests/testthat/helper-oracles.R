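# Independent brute-force oracles used to pin down expected values.

# All-pairs interaction permutation test: O(n^2) distances, nested-loop
# counting, same permutation stream as the package implementation
# (set.seed(seed), then n_perm draws of sample()).
naive_permutation_test <- function(coords, labels, radius, n_perm, seed) {
  coords <- as.matrix(coords)
  f <- as.factor(labels)
  li <- as.integer(f)
  K <- nlevels(f)
  n <- nrow(coords)
  d <- as.matrix(stats::dist(coords))
  count <- function(lab) {
    M <- matrix(0L, K, K)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (d[i, j] <= radius) {
          a <- min(lab[i], lab[j]); b <- max(lab[i], lab[j])
          M[a, b] <- M[a, b] + 1L
        }
      }
    }
    M + t(M) - diag(diag(M), K)
  }
  real <- count(li)
  gt <- matrix(0L, K, K); lt <- matrix(0L, K, K); acc <- matrix(0, K, K)
  set.seed(seed)
  for (p in seq_len(n_perm)) {
    M <- count(sample(li))
    gt <- gt + (M > real)
    lt <- lt + (M < real)
    acc <- acc + M
  }
  perm_mean <- acc / n_perm
  enr <- log2(real / perm_mean)
  enr[real == 0 | perm_mean == 0] <- NaN
  list(real_counts = real, perm_mean = perm_mean, log2_enrichment = enr,
       p_greater = (gt + 1) / (n_perm + 1), p_less = (lt + 1) / (n_perm + 1))
}

# Per-window mean by direct summation.
brute_window_means <- function(arr, window_zyx, step_zyx) {
  d <- dim(arr)
  zs <- seq(1, d[1] - window_zyx[1] + 1, by = step_zyx[1])
  ys <- seq(1, d[2] - window_zyx[2] + 1, by = step_zyx[2])
  xs <- seq(1, d[3] - window_zyx[3] + 1, by = step_zyx[3])
  out <- numeric(0)
  for (x0 in xs) for (y0 in ys) for (z0 in zs) {
    out <- c(out, mean(arr[z0:(z0 + window_zyx[1] - 1),
                           y0:(y0 + window_zyx[2] - 1),
                           x0:(x0 + window_zyx[3] - 1)]))
  }
  out
}

# Mean distance to the k nearest other positive pixels, brute force.
brute_knn_mean_dists <- function(image2d, k) {
  pos <- which(image2d > 0, arr.ind = TRUE)
  d <- as.matrix(stats::dist(pos))
  apply(d, 1, function(row) mean(sort(row)[2:(k + 1)]))
}

# Adjusted Rand index between two partitions.
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

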