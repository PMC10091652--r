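# Independent oracles and small fixtures shared across tests. Each oracle is
# coded directly from first principles, separate from the package's own
# implementation paths.

# Brute-force gene-set scoring: kernel CDF, symmetric rank statistic and
# enrichment walk evaluated with plain loops.
oracle_gsva <- function(X, sets, tau = 1, mx_diff = TRUE, min_size = 1) {
  keep <- apply(X, 1, sd) > 0
  X <- X[keep, , drop = FALSE]
  n <- ncol(X)
  z <- X * 0
  for (i in seq_len(nrow(X))) {
    h <- sd(X[i, ]) / 4
    for (j in seq_len(n)) z[i, j] <- mean(pnorm((X[i, j] - X[i, ]) / h))
  }
  p <- nrow(z)
  out <- matrix(NA_real_, length(sets), n,
                dimnames = list(names(sets), colnames(X)))
  for (si in seq_along(sets)) {
    memb <- rownames(z) %in% sets[[si]]
    if (sum(memb) < min_size) next
    for (j in seq_len(n)) {
      o <- order(-z[, j])
      rk <- integer(p); rk[o] <- seq_len(p)
      r <- abs(p / 2 - rk)
      w <- r[o]^tau * memb[o]
      num <- cumsum(w) / sum(w)
      den <- cumsum(!memb[o]) / (p - sum(memb))
      nu <- num - den
      out[si, j] <- if (mx_diff) max(c(0, nu)) + min(c(0, nu))
                    else nu[which.max(abs(nu))]
    }
  }
  out[!is.na(out[, 1]), , drop = FALSE]
}

# Step-by-step fusion oracle following the same update rule as snf_fuse but
# written independently (explicit loops, no shared helpers).
oracle_snf <- function(views, K, T) {
  n <- nrow(views[[1]])
  norm1 <- function(W) {
    A <- W; diag(A) <- 0
    x <- rep(1, n)
    for (i in 1:5000) {
      r <- as.vector(A %*% x)
      if (max(abs(x * r - 0.5)) < 1e-13) break
      x <- sqrt(x * 0.5 / r)
    }
    P <- A * outer(x, x); P <- (P + t(P)) / 2; diag(P) <- 0.5
    P
  }
  knn <- function(W, K) {
    S <- matrix(0, n, n)
    for (i in 1:n) {
      w <- W[i, ]; w[i] <- -Inf
      nb <- order(-w, seq_len(n))[1:K]
      S[i, nb] <- W[i, nb] / sum(W[i, nb])
    }
    S
  }
  m <- length(views)
  P <- lapply(views, norm1)
  S <- lapply(views, knn, K = K)
  for (it in seq_len(T)) {
    gap <- 0
    for (u in seq_len(m - 1)) for (v in (u + 1):m)
      gap <- max(gap, max(abs(P[[u]] - P[[v]])))
    if (gap < 1e-12) break
    newP <- P
    step <- 0
    for (v in seq_len(m)) {
      others <- Reduce(`+`, P[-v]) / (m - 1)
      Q <- S[[v]] %*% others %*% t(S[[v]])
      Q <- (Q + t(Q)) / 2
      newP[[v]] <- norm1(Q)
      step <- max(step, max(abs(newP[[v]] - P[[v]])))
    }
    P <- newP
    if (step < 1e-10) break
  }
  fused <- Reduce(`+`, P) / m
  norm1((fused + t(fused)) / 2)
}

# Classical Gaussian two-sample likelihood-ratio statistic (all data
# expressed, no covariates): 2 log LR = n log(RSS0 / RSS1).
oracle_gaussian_lrt <- function(y, group) {
  n <- length(y)
  rss0 <- sum((y - mean(y))^2)
  m1 <- tapply(y, group, mean)
  rss1 <- sum((y - m1[as.character(group)])^2)
  stat <- n * log(rss0 / rss1)
  pchisq(stat, df = 1, lower.tail = FALSE)
}

# Exact hypergeometric enrichment by enumeration over all draws.
oracle_hypergeom <- function(n_universe, n_ref, n_query, overlap) {
  total <- choose(n_universe, n_query)
  sum(vapply(overlap:min(n_ref, n_query), function(k)
    choose(n_ref, k) * choose(n_universe - n_ref, n_query - k),
    numeric(1))) / total
}

# A reduced cohort for unit tests (fast but structurally identical to the
# default study conditions).
small_config <- function(seed = 11L, ...) {
  defaults <- list(seed = seed,
                   cells_per_patient_per_type = 30L,
                   n_genes = 120L,
                   n_gene_sets = 12L,
                   genes_per_set = c(8L, 20L),
                   de_genes_per_subtype_per_type = 12L,
                   shifted_sets_per_subtype_per_type = 1L)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

toy_expr <- function(n_genes = 20, n_cells = 6, seed = 1) {
  set.seed(seed)
  X <- matrix(abs(rnorm(n_genes * n_cells)), n_genes, n_cells,
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              sprintf("c%d", seq_len(n_cells))))
  cells <- data.frame(cell_id = colnames(X), patient_id = "p1",
                      diagnosis = "case", cell_type = "t",
                      stringsAsFactors = FALSE)
  cell_expr(X, cells, data.frame(patient_id = "p1"))
}
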