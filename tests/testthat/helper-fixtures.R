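# Shared fixtures and independent oracles for the test suite. Oracles are
# written from first principles, separate from the package internals.

# Gaussian blobs whose centers differ in *profile* (direction), the regime a
# Pearson-correlation affinity can separate (it is invariant to shifting a
# whole latent vector by a constant).
make_profile_blobs <- function(n_per, centers, sd = 0.5, seed = 1) {
  set.seed(seed)
  z <- do.call(rbind, lapply(seq_along(centers), function(i) {
    ctr <- centers[[i]]
    matrix(stats::rnorm(n_per * length(ctr), rep(ctr, each = n_per), sd),
           n_per, length(ctr))
  }))
  rownames(z) <- paste0("cell_", seq_len(nrow(z)))
  list(z = z, labels = rep(seq_along(centers), each = n_per))
}

# Independent dense spectral clustering: full Pearson-derived similarity,
# explicit normalized Laplacian, eigenvectors of the k smallest eigenvalues,
# row normalization, k-means under the given seed.
oracle_dense_spectral <- function(z, k, seed) {
  n <- nrow(z)
  a <- (1 + stats::cor(t(z))) / 2
  diag(a) <- 0
  dinv <- 1 / sqrt(rowSums(a))
  l <- diag(n) - a * (dinv %o% dinv)
  l <- (l + t(l)) / 2
  eg <- eigen(l, symmetric = TRUE)
  ord <- order(eg$values)[seq_len(k)]
  v <- eg$vectors[, ord, drop = FALSE]
  nv <- sqrt(rowSums(v^2)); nv[nv == 0] <- 1
  v <- v / nv
  set.seed(seed)
  km <- suppressWarnings(
    stats::kmeans(v, centers = k, nstart = 50L, iter.max = 300L,
                  algorithm = "Lloyd"))
  as.integer(km$cluster)
}

# Exact minimum spanning tree weight by exhaustive enumeration of all
# labelled trees via Pruefer sequences (n^(n-2) trees; use only for n <= 8).
oracle_mst_weight <- function(d) {
  n <- nrow(d)
  stopifnot(n <= 8, n >= 2)
  if (n == 2) return(d[1, 2])
  tree_weight <- function(pruefer) {
    degree <- rep(1L, n)
    for (v in pruefer) degree[v] <- degree[v] + 1L
    w <- 0
    avail <- degree
    for (v in pruefer) {
      leaf <- which(avail == 1L)[1L]
      w <- w + d[leaf, v]
      avail[leaf] <- 0L
      avail[v] <- avail[v] - 1L
    }
    pair <- which(avail == 1L)
    w + d[pair[1L], pair[2L]]
  }
  seqs <- expand.grid(rep(list(seq_len(n)), n - 2))
  min(apply(as.matrix(seqs), 1L, tree_weight))
}

# Direct double-loop KL divergence.
oracle_kl <- function(p, q) {
  total <- 0
  for (i in seq_len(nrow(p))) for (j in seq_len(ncol(p))) {
    if (i != j && p[i, j] > 0) total <- total + p[i, j] * log(p[i, j] / q[i, j])
  }
  total
}

# Two-block affinity graph with no edges between blocks.
make_two_component_graph <- function(n1, n2, seed) {
  set.seed(seed)
  n <- n1 + n2
  a <- matrix(0, n, n)
  fill <- function(idx) {
    for (i in idx) for (j in idx) {
      if (i < j) a[i, j] <<- a[j, i] <<- stats::runif(1, 0.2, 1)
    }
  }
  fill(seq_len(n1)); fill(n1 + seq_len(n2))
  structure(list(A = a, k_nn = n - 1L), class = "affinity_graph")
}

# Fast training settings for tests that exercise mechanics, not accuracy.
tiny_vae_args <- list(epochs = 6L, warmup_epochs = 3L, n_realizations = 2L)
tiny_fs_args <- list(epochs = 5L)
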