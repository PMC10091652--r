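## Patient similarity networks: locally scaled affinity kernel, similarity
## network fusion by cross-diffusion, spectral clustering, eigen-gap /
## rotation-cost model selection, affinity-based silhouette.

#' Parameters for network fusion and clustering
#'
#' @param K number of neighbors for the local kernel and affinity scaling.
#' @param T number of cross-diffusion iterations.
#' @param mu kernel scale.
#' @param k_range candidate cluster numbers.
#' @param seed seed for k-means restarts.
#' @return list of class \code{snf_params}.
#' @export
snf_params <- function(K = 3L, T = 100L, mu = 0.5, k_range = 2:5, seed = 1L) {
  if (K < 1) stopf("K must be >= 1")
  if (T < 1) stopf("T must be >= 1")
  if (mu <= 0) stopf("mu must be positive")
  structure(list(K = as.integer(K), T = as.integer(T), mu = mu,
                 k_range = as.integer(k_range), seed = as.integer(seed)),
            class = "snf_params")
}

#' Squared Euclidean distances between patient profiles
#'
#' @param profiles patients x features matrix (>= 2 patients).
#' @param standardize center/scale each feature to unit variance first;
#'   constant features are dropped.
#' @return n x n symmetric matrix of squared distances, zero diagonal.
#' @export
squared_euclidean_distances <- function(profiles, standardize = TRUE) {
  x <- as.matrix(profiles)
  if (nrow(x) < 2) stopf("need at least 2 patients")
  if (standardize) {
    v <- apply(x, 2, var)
    x <- x[, v > 0, drop = FALSE]
    x <- scale(x)
  }
  d <- as.matrix(dist(x))^2
  diag(d) <- 0
  d
}

#' Locally scaled affinity kernel
#'
#' m_i is the mean of the K smallest off-diagonal distances of row i,
#' eps_ij = (m_i + m_j + d_ij) / 3, and (exponential kernel)
#' W_ij = exp(-d_ij / (mu * eps_ij)); the "density" variant uses a Gaussian
#' density of the distance with scale mu * eps_ij instead. W is symmetric
#' with unit diagonal.
#'
#' @param dist symmetric distance matrix with zero diagonal.
#' @param K number of neighbors for the local scale (K < n).
#' @param mu kernel scale.
#' @param kernel "exponential" (default) or "density".
#' @return symmetric affinity matrix, diag = 1.
#' @export
affinity_matrix <- function(dist, K = 3L, mu = 0.5,
                            kernel = c("exponential", "density")) {
  kernel <- match.arg(kernel)
  n <- nrow(dist)
  if (K >= n) stopf("K (%d) must be smaller than the number of patients (%d)", K, n)
  m <- vapply(seq_len(n), function(i)
    mean(sort(dist[i, -i])[seq_len(K)]), numeric(1))
  eps <- (outer(m, m, "+") + dist) / 3
  if (kernel == "exponential") {
    W <- exp(-dist / (mu * eps))
    W[dist == 0] <- 1          # includes the all-zero-distance case (0/0)
  } else {
    sig <- mu * eps
    sig[sig == 0] <- .Machine$double.eps
    W <- exp(-dist / (2 * sig^2)) / (sqrt(2 * pi) * sig)
    W <- W / max(W)
  }
  W <- (W + t(W)) / 2
  diag(W) <- 1
  dimnames(W) <- dimnames(dist)
  W
}

#' Full normalization of an affinity matrix
#'
#' Scales the off-diagonal part to a symmetric matrix whose rows each sum to
#' 1/2 (symmetric Sinkhorn balancing; the classical row-wise division
#' W_ij / (2 sum_{k != i} W_ik) is its first half-step) and sets the
#' diagonal to 1/2, so the result is symmetric, row-stochastic and keeps
#' self-similarity strongest. These properties are preserved exactly under
#' the fusion iteration.
#'
#' @param W symmetric nonnegative affinity matrix.
#' @param tol convergence tolerance on the row sums.
#' @return normalized matrix: symmetric, diag = 1/2, rows sum to 1.
#' @export
full_normalize <- function(W, tol = 1e-13) {
  off <- rowSums(W) - diag(W)
  if (any(off == 0)) {
    who <- rownames(W)[off == 0]
    if (is.null(who)) who <- which(off == 0)
    stopf("patient(s) with no off-diagonal affinity: %s",
          paste(head(who, 3), collapse = ", "))
  }
  A <- W
  diag(A) <- 0
  x <- rep(1, nrow(A))
  for (iter in 1:5000) {
    r <- drop(A %*% x)
    if (max(abs(x * r - 0.5)) < tol) break
    x <- sqrt(x * 0.5 / r)
  }
  P <- A * tcrossprod(x)
  P <- (P + t(P)) / 2
  diag(P) <- 0.5
  dimnames(P) <- dimnames(W)
  P
}

#' Row-stochastic K-nearest-neighbor kernel
#'
#' Keeps, per row, the K strongest off-diagonal affinities (ties broken by
#' ascending index) and renormalizes them to sum to one; everything else,
#' including the diagonal, is zero.
#'
#' @param W symmetric nonnegative affinity matrix.
#' @param K neighbors per row.
#' @return sparse row-stochastic matrix (base matrix with zeros).
#' @export
local_kernel <- function(W, K) {
  n <- nrow(W)
  if (K >= n) stopf("K must be smaller than n")
  S <- matrix(0, n, n, dimnames = dimnames(W))
  for (i in seq_len(n)) {
    w <- W[i, ]
    w[i] <- -Inf
    nbr <- order(-w, seq_len(n))[seq_len(K)]
    tot <- sum(W[i, nbr])
    if (tot == 0) stopf("all %d nearest neighbors of row %d have zero affinity", K, i)
    S[i, nbr] <- W[i, nbr] / tot
  }
  S
}

#' Fuse affinity views by iterative cross-diffusion
#'
#' Each view's normalized matrix is diffused through its K-nearest-neighbor
#' kernel against the average of the other views, symmetrized and
#' renormalized each iteration; the fused network is the renormalized mean
#' of the diffused views. A single view is simply normalized.
#'
#' @param views list of raw affinity matrices on the same patients.
#' @param params an \code{\link{snf_params}}.
#' @return fused normalized affinity matrix (rows sum to 1, diag 1/2).
#' @export
snf_fuse <- function(views, params = snf_params()) {
  if (length(views) == 0) stopf("need at least one view")
  ids <- rownames(views[[1]])
  for (v in views)
    if (!identical(rownames(v), ids)) stopf("patient order differs across views")
  if (length(views) == 1) return(full_normalize(views[[1]]))
  m <- length(views)
  P <- lapply(views, full_normalize)
  S <- lapply(views, local_kernel, K = params$K)
  pair_gap <- function(P) {
    g <- 0
    for (u in seq_len(m - 1)) for (v in (u + 1):m)
      g <- max(g, max(abs(P[[u]] - P[[v]])))
    g
  }
  # views already in consensus (e.g. identical inputs) are a fixed point:
  # the fused network is their common normalization, untouched
  for (iter in seq_len(params$T)) {
    if (pair_gap(P) < 1e-12) break
    step <- 0
    newP <- vector("list", m)
    for (v in seq_len(m)) {
      others <- Reduce(`+`, P[-v]) / (m - 1)
      Q <- S[[v]] %*% others %*% t(S[[v]])
      Q <- (Q + t(Q)) / 2
      newP[[v]] <- full_normalize(Q)
      step <- max(step, max(abs(newP[[v]] - P[[v]])))
    }
    P <- newP
    if (step < 1e-10) break   # diffusion converged before T iterations
  }
  fused <- Reduce(`+`, P) / m
  fused <- (fused + t(fused)) / 2
  full_normalize(fused)
}

laplacian_eigen <- function(P) {
  n <- nrow(P)
  d <- rowSums(P)
  dm <- 1 / sqrt(d)
  L <- diag(n) - (dm * P) * rep(dm, each = n)  # I - D^-1/2 P D^-1/2
  L <- (L + t(L)) / 2
  eigen(L, symmetric = TRUE)   # values in decreasing order
}

#' Spectral clustering of a normalized affinity matrix
#'
#' Rows of the k eigenvectors of the symmetric normalized Laplacian with the
#' smallest eigenvalues are unit-normalized and clustered by seeded k-means
#' (20+ restarts). Labels are relabeled by descending cluster size, ties by
#' first patient index, so results are deterministic under the seed.
#'
#' @param P normalized affinity matrix.
#' @param k number of clusters.
#' @param seed k-means seed.
#' @param nstart k-means restarts.
#' @return integer labels named by patient.
#' @export
spectral_cluster <- function(P, k, seed = 1L, nstart = 50L) {
  n <- nrow(P)
  if (k > n) stopf("k (%d) exceeds the number of patients (%d)", k, n)
  if (k == 1) return(setNames(rep(1L, n), rownames(P)))
  eig <- laplacian_eigen(P)
  V <- eig$vectors[, n:(n - k + 1), drop = FALSE]
  nrm <- sqrt(rowSums(V^2))
  nrm[nrm == 0] <- 1
  Z <- V / nrm
  km <- with_seed(seed, kmeans(Z, centers = k, nstart = nstart, iter.max = 100))
  labels <- relabel_clusters(km$cluster)
  names(labels) <- rownames(P)
  labels
}

# Relabel: 1 = largest cluster, ties broken by smallest first-member index.
relabel_clusters <- function(cl) {
  sizes <- table(cl)
  first <- tapply(seq_along(cl), cl, min)
  ord <- order(-as.vector(sizes), as.vector(first))
  map <- setNames(seq_along(ord), names(sizes)[ord])
  as.integer(map[as.character(cl)])
}

#' Estimate the number of clusters from the fused network
#'
#' Eigen-gap criterion: with Laplacian eigenvalues lambda_1 <= ... <=
#' lambda_n, the best k maximizes lambda_(k+1) - lambda_k over the candidate
#' range. Rotation-cost criterion: for each k the leading k eigenvectors are
#' row-normalized and the alignment cost sum_i 1 / max_j Z_ij^2 (smaller =
#' cleaner indicator structure) is minimized.
#'
#' @param P normalized affinity matrix.
#' @param k_range candidate cluster numbers (max < n).
#' @return list with \code{best_k_eigengap}, \code{best_k_rotation} and a
#'   \code{diagnostics} data.frame (k, eigengap, rotation_cost).
#' @export
estimate_n_clusters <- function(P, k_range = 2:5) {
  n <- nrow(P)
  if (max(k_range) >= n) stopf("max(k_range) must be below the patient count")
  eig <- laplacian_eigen(P)
  lambda <- rev(eig$values)               # ascending
  gaps <- vapply(k_range, function(k) lambda[k + 1] - lambda[k], numeric(1))
  rot <- vapply(k_range, function(k) {
    V <- eig$vectors[, n:(n - k + 1), drop = FALSE]
    # align the eigenbasis to axes (varimax) before scoring row alignment
    if (k > 1) V <- V %*% stats::varimax(V, normalize = FALSE)$rotmat
    nrm <- sqrt(rowSums(V^2))
    nrm[nrm == 0] <- 1
    Z <- (V / nrm)^2
    sum(1 / apply(Z, 1, max))
  }, numeric(1))
  list(best_k_eigengap = k_range[which.max(gaps)],
       best_k_rotation = k_range[which.min(rot)],
       diagnostics = data.frame(k = k_range, eigengap = gaps,
                                rotation_cost = rot))
}

#' Silhouette coefficient from an affinity matrix
#'
#' Affinities are turned into distances by locally scaled similarity:
#' s_ij = P_ij / max_(k != i) P_ik per row, symmetrized, and d = 1 - s
#' (zero diagonal); the standard mean silhouette is then computed. The
#' per-row scaling makes the score independent of cluster-size-driven
#' differences in absolute affinity (rows of a row-stochastic network spread
#' their mass over more neighbors in larger clusters). Singleton clusters
#' contribute s(i) = 0.
#'
#' @param P normalized affinity matrix.
#' @param labels cluster labels (>= 2 nonempty clusters).
#' @return mean silhouette width in [-1, 1].
#' @export
silhouette_from_affinity <- function(P, labels) {
  if (length(unique(labels)) < 2) stopf("silhouette needs >= 2 clusters")
  n <- nrow(P)
  off <- P
  diag(off) <- NA
  rmax <- apply(off, 1, max, na.rm = TRUE)
  rmax[rmax == 0] <- 1
  s_sim <- off / rmax
  s_sim <- (s_sim + t(s_sim)) / 2
  d <- 1 - s_sim
  diag(d) <- 0
  s <- vapply(seq_len(n), function(i) {
    own <- which(labels == labels[i])
    own <- setdiff(own, i)
    if (length(own) == 0) return(0)
    a <- mean(d[i, own])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(l)
      mean(d[i, labels == l]), numeric(1)))
    if (max(a, b) == 0) return(0)
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

#' Build one affinity view per profile matrix and fuse them
#'
#' Convenience wrapper: standardized squared distances -> affinity kernel
#' per view -> \code{\link{snf_fuse}}.
#'
#' @param profile_list list of patients x features matrices (same patients).
#' @param params an \code{\link{snf_params}}.
#' @param standardize passed to \code{\link{squared_euclidean_distances}}.
#' @return fused normalized affinity matrix.
#' @export
fuse_views <- function(profile_list, params = snf_params(), standardize = TRUE) {
  views <- lapply(profile_list, function(pr)
    affinity_matrix(squared_euclidean_distances(pr, standardize),
                    K = params$K, mu = params$mu))
  snf_fuse(views, params)
}

#' Cluster patients from a fused network with model selection
#'
#' @param P fused normalized affinity matrix.
#' @param params an \code{\link{snf_params}}.
#' @param k optional fixed number of clusters (otherwise eigen-gap choice).
#' @return list of class \code{subtype_assignment}: labels, k, silhouette,
#'   selection diagnostics.
#' @export
subtype_patients <- function(P, params = snf_params(), k = NULL) {
  sel <- estimate_n_clusters(P, params$k_range)
  if (is.null(k)) k <- sel$best_k_eigengap
  labels <- spectral_cluster(P, k, seed = params$seed)
  structure(list(labels = labels, k = k,
                 silhouette = silhouette_from_affinity(P, labels),
                 selection = sel),
            class = "subtype_assignment")
}
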