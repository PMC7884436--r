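# Cell segregation on the compressed space: k-nearest-neighbour spectral
# clustering on a Pearson-similarity graph, cluster-number estimation from
# two sum-of-squares indices, weighted meta-clustering (wMetaC) consensus
# over replicate projections, and a k-nn voting procedure for large data.

#' Build the sparse k-nearest-neighbour affinity graph
#'
#' Pairwise similarity between cells is derived from Pearson correlation of
#' their latent vectors, mapped to `[0, 1]` as `s = (1 + r) / 2` so the
#' graph Laplacian stays well defined. Each cell keeps only its `k_nn` most
#' similar neighbours (the rest are zeroed) and the matrix is symmetrized
#' with `max(A, t(A))`.
#'
#' @param z compressed matrix (cells x latent dimensions).
#' @param k_nn number of neighbours kept per cell; default
#'   `min(n - 1, ceiling(sqrt(n)))`.
#' @return object of class `affinity_graph`: list with the symmetric
#'   matrix `A` (zero diagonal) and `k_nn`.
#' @export
build_knn_affinity <- function(z, k_nn = NULL) {
  stopifnot(is.matrix(z), nrow(z) >= 2L)
  n <- nrow(z)
  if (is.null(k_nn)) k_nn <- min(n - 1L, ceiling(sqrt(n)))
  k_nn <- as.integer(k_nn)
  if (k_nn < 1L || k_nn > n - 1L) stop("k_nn must be in [1, n-1]", call. = FALSE)
  sds <- apply(z, 1L, stats::sd)
  if (any(sds == 0)) {
    bad <- which(sds == 0)[1]
    stop(sprintf("cell %s has zero variance across latent dimensions",
                 rownames(z)[bad] %||% as.character(bad)), call. = FALSE)
  }
  s <- (1 + row_cor(z)) / 2
  diag(s) <- 0
  a <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- order(s[i, ], decreasing = TRUE)[seq_len(k_nn)]
    a[i, nb] <- s[i, nb]
  }
  a <- pmax(a, t(a))
  dimnames(a) <- list(rownames(z), rownames(z))
  structure(list(A = a, k_nn = k_nn), class = "affinity_graph")
}

# Symmetric normalized Laplacian L = I - D^{-1/2} A D^{-1/2}.
laplacian_sym <- function(a) {
  d <- rowSums(a)
  d[d <= 0] <- .Machine$double.eps  # isolated node guard
  dinv <- 1 / sqrt(d)
  l <- -a * tcrossprod(dinv)
  diag(l) <- diag(l) + 1
  (l + t(l)) / 2
}

# Eigenvectors of the k smallest eigenvalues of L^sym, rows L2-normalized.
spectral_embedding <- function(a, k) {
  l <- laplacian_sym(a)
  eg <- tryCatch(eigen(l, symmetric = TRUE),
                 error = function(e) stop(
                   "eigendecomposition failed (try a larger k_nn): ",
                   conditionMessage(e), call. = FALSE))
  n <- nrow(l)
  v <- eg$vectors[, n:(n - k + 1L), drop = FALSE]  # ascending eigenvalues
  nrm <- sqrt(rowSums(v^2))
  nrm[nrm == 0] <- 1
  list(vectors = v / nrm, values = rev(eg$values)[seq_len(k)],
       all_values = rev(eg$values))
}

#' k-nearest-neighbour spectral clustering
#'
#' The four classical steps on a sparse affinity graph: (i) the affinity
#' matrix `A`, (ii) the symmetric normalized Laplacian
#' `L = I - D^{-1/2} A D^{-1/2}`, (iii) the eigenvectors of the `k`
#' smallest eigenvalues (rows L2-normalized), (iv) k-means on those
#' eigenvector rows (50 restarts under the given seed).
#'
#' @param g an `affinity_graph` from [build_knn_affinity()].
#' @param k number of clusters, `2 <= k <= n`.
#' @param seed seed for the k-means restarts.
#' @param nstart k-means restarts (default 50).
#' @return integer vector of 1-based cluster labels.
#' @export
knn_spectral_cluster <- function(g, k, seed = 1L, nstart = 50L) {
  stopifnot(inherits(g, "affinity_graph"))
  n <- nrow(g$A)
  k <- as.integer(k)
  if (k < 2L || k > n) stop("k must be in [2, n]", call. = FALSE)
  emb <- spectral_embedding(g$A, k)
  set.seed(seed)
  # Lloyd instead of Hartigan-Wong: the near-duplicate rows of a crisp
  # spectral embedding thrash HW's Quick-TRANSfer stage; Lloyd's routine
  # empty-cluster/convergence warnings are handled by the restarts
  km <- suppressWarnings(
    stats::kmeans(emb$vectors, centers = k, nstart = nstart,
                  iter.max = 300L, algorithm = "Lloyd"))
  as.integer(km$cluster)
}

# Sum-of-squares decomposition of an embedding under a labeling.
ss_decompose <- function(v, labels) {
  center <- colMeans(v)
  ss_total <- sum(sweep(v, 2L, center)^2)
  ss_within <- 0
  for (cl in unique(labels)) {
    rows <- v[labels == cl, , drop = FALSE]
    ss_within <- ss_within + sum(sweep(rows, 2L, colMeans(rows))^2)
  }
  c(total = ss_total, within = ss_within, between = ss_total - ss_within)
}

#' Scan cluster numbers and score each with two sum-of-squares indices
#'
#' For every candidate cluster number `j` the subsampled cells are clustered
#' with [knn_spectral_cluster()] in the `j`-eigenvector embedding, and two
#' indices are recorded: `Index1(j) = SS_between / SS_total` (separation;
#' in `[0, 1]`) and `Index2(j) = (SS_within(j+1) - SS_within(j)) /
#' SS_within(j)`, the relative jump in within-cluster scatter when one more
#' eigenvector/cluster is added. Each `SS` is computed in the embedding used
#' at that `j`, so `SS_between + SS_within = SS_total` holds per scan point.
#'
#' @param z compressed matrix.
#' @param j_range candidate cluster counts (default `2:15`).
#' @param subsample number of cells scanned (default `min(n, 2000)`),
#'   sampled uniformly without replacement under `seed`.
#' @param k_nn,seed as in [build_knn_affinity()] / [knn_spectral_cluster()].
#' @return data frame with columns `j`, `ss_total`, `ss_within`,
#'   `ss_between`, `index1`, `index2` (NA at the last scanned `j`).
#' @export
cluster_index_scan <- function(z, j_range = 2:15, subsample = NULL,
                               k_nn = NULL, seed = 1L) {
  n <- nrow(z)
  if (is.null(subsample)) subsample <- min(n, 2000L)
  if (subsample < max(j_range) + 1L) {
    stop("subsample must exceed the largest candidate cluster count", call. = FALSE)
  }
  set.seed(seed)
  sub <- if (subsample < n) sort(sample.int(n, subsample)) else seq_len(n)
  zs <- z[sub, , drop = FALSE]
  g <- build_knn_affinity(zs, k_nn = k_nn)
  js <- sort(unique(as.integer(j_range)))
  scan_js <- c(js, max(js) + 1L)  # Index2 needs SS_within at j+1
  ss <- matrix(NA_real_, length(scan_js), 3,
               dimnames = list(NULL, c("total", "within", "between")))
  for (i in seq_along(scan_js)) {
    j <- scan_js[i]
    emb <- spectral_embedding(g$A, j)
    set.seed(derive_seed(seed, j))
    km <- suppressWarnings(
      stats::kmeans(emb$vectors, centers = j, nstart = 50L,
                    iter.max = 300L, algorithm = "Lloyd"))
    ss[i, ] <- ss_decompose(emb$vectors, km$cluster)
  }
  keep <- seq_along(js)
  w <- ss[, "within"]
  index2 <- (w[keep + 1L] - w[keep]) / pmax(w[keep], .Machine$double.eps)
  data.frame(
    j = js,
    ss_total = ss[keep, "total"],
    ss_within = ss[keep, "within"],
    ss_between = ss[keep, "between"],
    index1 = ss[keep, "between"] / pmax(ss[keep, "total"], .Machine$double.eps),
    index2 = index2
  )
}

#' Predict the number of cell types
#'
#' Combines the two indices of [cluster_index_scan()]. `k1` is the largest
#' `j` whose `Index1` comes within 0.005 of the scan maximum: in the
#' per-`j` spectral embeddings the separation ratio peaks at the true
#' cluster count and degrades once noise eigenvectors enter, so the last
#' `j` attaining the peak marks the boundary. `k2` detects the `Index2`
#' spike — the first added eigenvector that inflates within-cluster
#' scatter — as the largest `j` whose within-SS is still negligible
#' (at most 0.5% of the total SS); when the data are never that crisp the
#' fallback is the `j` maximizing the relative jump
#' `(SS_within(j+1) - SS_within(j)) / max(SS_within(j), 0.005 SS_total(j))`,
#' whose floored denominator keeps the ratio meaningful when perfectly
#' separated clusters drive `SS_within` to exactly zero. The prediction is
#' the mean of `k1` and `k2`, rounded half up.
#'
#' @inheritParams cluster_index_scan
#' @return integer: the predicted number of clusters; the scan table is
#'   attached as attribute `scan`, `k1`/`k2` as attributes.
#' @export
predict_n_clusters <- function(z, j_range = 2:15, subsample = NULL,
                               k_nn = NULL, seed = 1L) {
  scan <- cluster_index_scan(z, j_range = j_range, subsample = subsample,
                             k_nn = k_nn, seed = seed)
  k1 <- scan$j[max(which(scan$index1 >= max(scan$index1) - 0.005))]
  crisp <- which(scan$ss_within <= 0.005 * scan$ss_total)
  if (length(crisp)) {
    k2 <- scan$j[max(crisp)]
  } else {
    dw <- c(diff(scan$ss_within), NA)
    spike <- dw / pmax(scan$ss_within, 0.005 * scan$ss_total)
    k2 <- scan$j[which.max(spike)]
  }
  k <- as.integer(floor((k1 + k2) / 2 + 0.5))  # round half up
  attr(k, "k1") <- k1; attr(k, "k2") <- k2; attr(k, "scan") <- scan
  k
}

# Canonicalize labels to contiguous 1..k in order of first appearance.
canonical_labels <- function(labels) {
  as.integer(factor(labels, levels = unique(labels)))
}

#' Weighted meta-clustering consensus (wMetaC)
#'
#' Combines replicate partitions in five steps: (i) the cell-cell
#' co-clustering chance `s_ij` across replicates gives weights
#' `w_ij = s_ij (1 - s_ij)` (maximal at `s = 0.5`, i.e. for the ambiguous
#' pairs); (ii) each cell is weighted by its row sum of `w`; (iii) every
#' cluster of every replicate becomes one element of the cluster union `C`
#' and cluster-cluster similarity is the cell-weighted Jaccard overlap of
#' member sets; (iv) average-linkage hierarchical clustering cuts `C` into
#' `k` meta-clusters; (v) each cell votes with its replicate memberships
#' and takes the majority meta-cluster. When all replicates agree exactly
#' (all `w_ij = 0`) the common partition is returned directly.
#'
#' @param replicate_labels list of equal-length cluster label vectors.
#' @param k number of consensus clusters; default: the most common cluster
#'   count among replicates (larger count on ties).
#' @return integer vector of 1-based consensus labels.
#' @export
consensus_wmetac <- function(replicate_labels, k = NULL) {
  stopifnot(is.list(replicate_labels), length(replicate_labels) >= 1L)
  n <- length(replicate_labels[[1L]])
  if (!all(vapply(replicate_labels, length, 1L) == n)) {
    stop("replicate label vectors have unequal lengths", call. = FALSE)
  }
  reps <- lapply(replicate_labels, canonical_labels)
  nr <- length(reps)
  if (is.null(k)) {
    counts <- vapply(reps, max, 1L)
    tab <- table(counts)
    k <- max(as.integer(names(tab)[tab == max(tab)]))
  }

  # (i) co-clustering chance via indicator cross-products
  s <- matrix(0, n, n)
  for (r in reps) {
    ind <- outer(r, sort(unique(r)), "==") * 1
    s <- s + tcrossprod(ind)
  }
  s <- s / nr
  w <- s * (1 - s)
  if (all(w == 0)) return(reps[[1L]])  # perfect agreement across replicates

  # (ii) cell weights
  cw <- rowSums(w) + 1e-12

  # (iii) cluster union and weighted-Jaccard similarity
  members <- list()
  owner_rep <- integer(0)
  for (ri in seq_len(nr)) {
    for (cl in sort(unique(reps[[ri]]))) {
      members[[length(members) + 1L]] <- which(reps[[ri]] == cl)
      owner_rep <- c(owner_rep, ri)
    }
  }
  nc <- length(members)
  sim <- matrix(0, nc, nc)
  for (a in seq_len(nc)) {
    for (b in a:nc) {
      inter <- intersect(members[[a]], members[[b]])
      uni <- union(members[[a]], members[[b]])
      sim[a, b] <- sim[b, a] <- sum(cw[inter]) / sum(cw[uni])
    }
  }

  # (iv) hierarchical clustering of the cluster-cluster matrix
  hc <- stats::hclust(stats::as.dist(1 - sim), method = "average")
  meta <- stats::cutree(hc, k = min(k, nc))

  # (v) voting: each cell's replicate memberships name meta-clusters
  votes <- matrix(0, n, max(meta))
  offset <- 0L
  for (ri in seq_len(nr)) {
    cls <- sort(unique(reps[[ri]]))
    for (ci in seq_along(cls)) {
      mc <- meta[offset + ci]
      rows <- members[[offset + ci]]
      votes[rows, mc] <- votes[rows, mc] + 1
    }
    offset <- offset + length(cls)
  }
  canonical_labels(max.col(votes, ties.method = "first"))
}

#' Assign remaining cells to core clusters by k-nn voting
#'
#' For data too large to cluster in full, only a core subset is clustered
#' and every remaining cell takes the majority label of its `k_vote` most
#' Pearson-similar core cells; ties go to the label of the single most
#' similar neighbour.
#'
#' @param core_labels labels of the core cells (ordered as `core_idx`).
#' @param z full compressed matrix.
#' @param core_idx row indices of the core cells in `z`.
#' @param k_vote neighbours consulted per cell (default 10, capped at the
#'   core size).
#' @return integer labels for all rows of `z`; core rows keep their labels.
#' @export
vote_assign <- function(core_labels, z, core_idx, k_vote = 10L) {
  n <- nrow(z)
  if (length(core_idx) == 0L) stop("core subset is empty", call. = FALSE)
  stopifnot(length(core_labels) == length(core_idx))
  k_vote <- min(as.integer(k_vote), length(core_idx))
  labels <- integer(n)
  labels[core_idx] <- core_labels
  rest <- setdiff(seq_len(n), core_idx)
  if (length(rest)) {
    sim <- row_cor(z[rest, , drop = FALSE], z[core_idx, , drop = FALSE])
    for (i in seq_along(rest)) {
      nb <- order(sim[i, ], decreasing = TRUE)[seq_len(k_vote)]
      tal <- table(core_labels[nb])
      top <- as.integer(names(tal)[tal == max(tal)])
      labels[rest[i]] <- if (length(top) == 1L) top else core_labels[nb[1L]]
    }
  }
  labels
}

#' Full cell-segregation pipeline on a filtered matrix
#'
#' Repeats the stochastic projection-and-clustering process: trains
#' `n_replicates` stacked Bayesian autoencoders under derived seeds,
#' clusters each compressed space with [knn_spectral_cluster()] (the
#' cluster number is predicted once from the first replicate's latent space
#' when not supplied), and merges the replicate partitions with
#' [consensus_wmetac()]. When `n > vote_threshold` only a random core of
#' `core_size` cells is clustered and the rest are assigned by
#' [vote_assign()].
#'
#' @param x_filtered scaled, gene-filtered matrix (cells x genes).
#' @param n_replicates number of projection/clustering replicates
#'   (default 10).
#' @param k number of clusters; `NULL` (default) predicts it.
#' @param k_nn neighbours for the affinity graph (default
#'   `min(n-1, ceiling(sqrt(n)))`).
#' @param seed master seed; replicate seeds are derived from it.
#' @param vote_threshold cell count above which the voting procedure
#'   activates (default 50000).
#' @param core_size core subset size for voting (default `min(n, 2000)`).
#' @param vae_args list of extra arguments for [train_stacked_vae()]
#'   (e.g. `epochs`, `warmup_epochs`).
#' @return object of class `clustering_result`: list with `labels`
#'   (consensus, 1-based contiguous), `k`, `replicate_labels`, `latent`
#'   (first replicate's compressed matrix), and metadata.
#' @export
cluster_cells <- function(x_filtered, n_replicates = 10L, k = NULL,
                          k_nn = NULL, seed = 1L, vote_threshold = 50000L,
                          core_size = 2000L, vae_args = list()) {
  validate_expression_matrix(x_filtered)
  n <- nrow(x_filtered)
  use_voting <- n > vote_threshold
  core_idx <- seq_len(n)
  if (use_voting) {
    set.seed(derive_seed(seed, 777L))
    core_idx <- sort(sample.int(n, min(n, core_size)))
  }

  replicate_labels <- vector("list", n_replicates)
  latent1 <- NULL
  for (r in seq_len(n_replicates)) {
    rseed <- derive_seed(seed, r)
    vae <- do.call(train_stacked_vae,
                   c(list(x = x_filtered, seed = rseed), vae_args))
    z <- encode_cells(vae, x_filtered)
    if (r == 1L) {
      latent1 <- z
      if (is.null(k)) {
        k <- predict_n_clusters(z[core_idx, , drop = FALSE], seed = rseed)
        message("predicted number of clusters: ", as.integer(k))
      }
    }
    g <- build_knn_affinity(z[core_idx, , drop = FALSE], k_nn = k_nn)
    core_lab <- knn_spectral_cluster(g, k = as.integer(k), seed = rseed)
    replicate_labels[[r]] <- if (use_voting) {
      vote_assign(core_lab, z, core_idx)
    } else {
      core_lab
    }
  }

  labels <- canonical_labels(consensus_wmetac(replicate_labels,
                                              k = as.integer(k)))
  structure(list(
    labels = labels, k = as.integer(k),
    replicate_labels = replicate_labels, latent = latent1,
    metadata = list(seed = seed, k_nn = k_nn, n_replicates = n_replicates,
                    voting = use_voting)
  ), class = "clustering_result")
}
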