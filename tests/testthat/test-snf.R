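test_that("squared Euclidean distances match hand values and symmetry", {
  pr <- matrix(c(0, 3), 2, 1, dimnames = list(c("a", "b"), NULL))
  d <- squared_euclidean_distances(pr, standardize = FALSE)
  expect_equal(d["a", "b"], 9)
  expect_equal(diag(d), c(a = 0, b = 0))
  set.seed(1)
  x <- matrix(rnorm(20), 5, 4)
  d2 <- squared_euclidean_distances(x)
  expect_equal(d2, t(d2))
  expect_equal(squared_euclidean_distances(x[c(1, 1), , drop = FALSE],
                                           standardize = FALSE)[1, 2], 0)
  expect_error(squared_euclidean_distances(x[1, , drop = FALSE]), "2 patients")
})

test_that("locally scaled kernel matches hand arithmetic", {
  # points on a line at 0, 1, 10 with K = 1, mu = 0.5:
  # m = (1, 1, 9); eps_12 = (1 + 1 + 1)/3 = 1; W_12 = exp(-1/0.5) = exp(-2)
  dd <- as.matrix(dist(c(0, 1, 10)))
  W <- affinity_matrix(dd, K = 1, mu = 0.5)
  expect_equal(W[1, 2], exp(-2), tolerance = 1e-12)
  expect_equal(unname(diag(W)), rep(1, 3))
  # all-zero distances give the all-ones kernel
  expect_true(all(affinity_matrix(matrix(0, 3, 3), K = 1, mu = 0.5) == 1))
  # monotone decreasing in distance at fixed local scales
  W2 <- affinity_matrix(as.matrix(dist(c(0, 1, 2, 10))), K = 2, mu = 0.5)
  expect_gt(W2[1, 2], W2[1, 4])
  expect_error(affinity_matrix(dd, K = 3, mu = 0.5), "smaller")
})

test_that("full normalization yields symmetric unit-row-sum matrices", {
  W <- matrix(c(1, 5, 5, 1), 2, 2)
  expect_equal(full_normalize(W), matrix(0.5, 2, 2))
  W4 <- matrix(1, 4, 4)
  P4 <- full_normalize(W4)
  expect_equal(P4[1, 2], 1 / 6)
  set.seed(3)
  Wr <- matrix(runif(36), 6, 6); Wr <- (Wr + t(Wr)) / 2; diag(Wr) <- 1
  P <- full_normalize(Wr)
  expect_lt(max(abs(rowSums(P) - 1)), 1e-12)
  expect_equal(P, t(P))
  expect_equal(diag(P), rep(0.5, 6))
  Wz <- diag(3)
  expect_error(full_normalize(Wz), "no off-diagonal affinity")
})

test_that("the local kernel keeps K neighbors per row and is row-stochastic", {
  set.seed(4)
  W <- matrix(runif(49), 7, 7); W <- (W + t(W)) / 2; diag(W) <- 1
  S <- local_kernel(W, 3)
  expect_true(all(rowSums(S > 0) == 3))
  expect_lt(max(abs(rowSums(S) - 1)), 1e-12)
  # K = n - 1 gives the off-diagonal row normalization of W
  S6 <- local_kernel(W, 6)
  Woff <- W; diag(Woff) <- 0
  expect_equal(S6, Woff / rowSums(Woff), ignore_attr = TRUE)
})

test_that("fusing identical views returns the normalized view exactly", {
  set.seed(1)
  X <- matrix(rnorm(24), 6, 4, dimnames = list(paste0("p", 1:6), NULL))
  W <- affinity_matrix(squared_euclidean_distances(X), K = 2)
  for (m in 2:3) {
    f <- snf_fuse(rep(list(W), m), snf_params(K = 2, T = 100))
    expect_lt(max(abs(f - full_normalize(W))), 1e-8)
  }
})

test_that("fusion matches the independently coded step-by-step oracle", {
  set.seed(9)
  blocks <- rep(1:2, each = 2)
  mk_view <- function(noise) {
    A <- matrix(runif(16) * noise, 4, 4); A <- (A + t(A)) / 2
    for (b in 1:2) A[blocks == b, blocks == b] <- A[blocks == b, blocks == b] + 1
    diag(A) <- 1
    dimnames(A) <- list(paste0("p", 1:4), paste0("p", 1:4))
    A
  }
  views <- list(mk_view(0.1), mk_view(0.2))
  f <- snf_fuse(views, snf_params(K = 2, T = 5))
  expect_lt(max(abs(f - oracle_snf(views, K = 2, T = 5))), 1e-10)
  # conservation: symmetric, rows sum to 1, diag 1/2
  expect_equal(f, t(f))
  expect_lt(max(abs(rowSums(f) - 1)), 1e-8)
  expect_equal(diag(f), setNames(rep(0.5, 4), paste0("p", 1:4)))
  # order invariance
  expect_equal(snf_fuse(rev(views), snf_params(K = 2, T = 5)), f,
               tolerance = 1e-12)
  # patient order mismatch is rejected
  v2 <- views[[2]][4:1, 4:1]
  expect_error(snf_fuse(list(views[[1]], v2), snf_params(K = 2, T = 5)),
               "order differs")
})

planted_affinity <- function(seed = 2, noise = 0.05,
                             sizes = c(6, 4, 5)) {
  set.seed(seed)
  n <- sum(sizes)
  blocks <- rep(seq_along(sizes), sizes)
  A <- matrix(runif(n * n) * noise, n, n); A <- (A + t(A)) / 2
  for (b in seq_along(sizes))
    A[blocks == b, blocks == b] <- A[blocks == b, blocks == b] + 1
  diag(A) <- 1
  dimnames(A) <- list(paste0("p", 1:n), paste0("p", 1:n))
  list(A = A, blocks = blocks)
}

test_that("spectral clustering recovers blocks and is deterministic", {
  pa <- planted_affinity()
  P <- full_normalize(pa$A)
  lab <- spectral_cluster(P, 3, seed = 1)
  expect_equal(adjusted_rand_index(lab, pa$blocks), 1)
  expect_identical(lab, spectral_cluster(P, 3, seed = 1))
  # exact 2-block (disconnected) affinity
  B <- matrix(0, 4, 4); B[1:2, 1:2] <- 1; B[3:4, 3:4] <- 1
  dimnames(B) <- list(paste0("p", 1:4), paste0("p", 1:4))
  lb <- spectral_cluster(full_normalize(B), 2, seed = 1)
  expect_equal(adjusted_rand_index(lb, c(1, 1, 2, 2)), 1)
  expect_equal(unname(spectral_cluster(P, 1)), rep(1L, 15))
  expect_error(spectral_cluster(P, 99), "exceeds")
  # relabeling: cluster 1 is the largest
  expect_equal(as.integer(names(which.max(table(lab)))), 1L)
})

test_that("cluster-number estimation finds the planted k", {
  for (sizes in list(c(6, 4, 5), c(5, 5))) {
    pa <- planted_affinity(seed = 3, noise = 0, sizes = sizes)
    sel <- estimate_n_clusters(full_normalize(pa$A), 2:5)
    expect_equal(sel$best_k_eigengap, length(sizes))
    expect_equal(sel$best_k_rotation, length(sizes))
  }
  pa <- planted_affinity(seed = 2, noise = 0.05)
  sel <- estimate_n_clusters(full_normalize(pa$A), 2:5)
  expect_equal(sel$best_k_eigengap, 3)
  expect_equal(sel$best_k_rotation, 3)
  expect_error(estimate_n_clusters(full_normalize(pa$A), 2:20), "below")
})

test_that("affinity silhouette behaves like a cluster-quality score", {
  pa <- planted_affinity(seed = 5, noise = 0.01)
  P <- full_normalize(pa$A)
  s_true <- silhouette_from_affinity(P, pa$blocks)
  expect_gt(s_true, 0.5)
  expect_true(s_true >= -1 && s_true <= 1)
  # perfectly separated two blocks approach 1
  B <- matrix(1e-6, 8, 8); B[1:4, 1:4] <- 1; B[5:8, 5:8] <- 1; diag(B) <- 1
  expect_gt(silhouette_from_affinity(full_normalize(B), rep(1:2, each = 4)),
            0.95)
  # random labels on a uniform affinity sit near zero
  U <- matrix(1, 10, 10)
  set.seed(8)
  s_rand <- replicate(20,
    silhouette_from_affinity(full_normalize(U + 0), sample(rep(1:2, 5))))
  expect_lt(abs(mean(s_rand)), 0.1)
  expect_error(silhouette_from_affinity(P, rep(1, 15)), "2 clusters")
})

test_that("adjusted Rand index agrees with the mclust reference", {
  skip_if_not_installed("mclust")
  set.seed(6)
  for (i in 1:10) {
    a <- sample(1:3, 20, replace = TRUE)
    b <- sample(1:4, 20, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
  expect_equal(adjusted_rand_index(1:5, c(2, 3, 4, 5, 1)), 1)
})
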