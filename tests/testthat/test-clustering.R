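test_that("affinity graph maps Pearson correlation onto [0, 1] similarities", {
  z <- rbind(c(1, 2, 3, 4), c(2, 4, 6, 8), c(4, 3, 2, 1))
  rownames(z) <- c("a", "b", "c")
  g <- build_knn_affinity(z, k_nn = 2)
  expect_equal(g$A["a", "b"], 1)     # perfectly correlated pair
  expect_equal(g$A["a", "c"], 0)     # anti-correlated pair
  expect_equal(diag(g$A), rep(0, 3), ignore_attr = TRUE)
  expect_identical(g$A, t(g$A))
})

test_that("k_nn = n - 1 reproduces the dense similarity matrix", {
  set.seed(1)
  z <- matrix(rnorm(60), 12, 5)
  g <- build_knn_affinity(z, k_nn = 11)
  s <- (1 + cor(t(z))) / 2
  diag(s) <- 0
  expect_equal(g$A, s, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("zero-variance cells are rejected by name", {
  z <- rbind(a = c(1, 1, 1), b = c(1, 2, 3), c = c(3, 1, 2))
  expect_error(build_knn_affinity(z, k_nn = 2), "a.*zero variance")
})

test_that("spectral clustering agrees with a dense independent oracle", {
  for (i in 1:8) {
    set.seed(i)
    n <- sample(10:50, 1); k <- sample(2:4, 1)
    z <- matrix(rnorm(n * 6), n, 6)
    ours <- knn_spectral_cluster(build_knn_affinity(z, k_nn = n - 1), k,
                                 seed = 1000 + i)
    oracle <- oracle_dense_spectral(z, k, seed = 1000 + i)
    expect_equal(adjusted_rand_index(ours, oracle), 1)
  }
})

test_that("two-component graphs give two zero eigenvalues and the exact split", {
  for (i in 1:5) {
    n1 <- sample(3:8, 1); n2 <- sample(3:8, 1)
    g <- make_two_component_graph(n1, n2, seed = i)
    emb <- schae:::spectral_embedding(g$A, 2)
    expect_equal(sum(abs(emb$all_values) < 1e-8), 2)
    labs <- knn_spectral_cluster(g, 2, seed = i)
    expect_equal(adjusted_rand_index(labs, rep(1:2, c(n1, n2))), 1)
  }
})

test_that("well-separated latent blobs are recovered exactly", {
  fx <- make_profile_blobs(40, list(c(3, 3, 0, 0, 0), c(0, 0, 0, 3, 3)),
                           sd = 0.4, seed = 5)
  labs <- knn_spectral_cluster(build_knn_affinity(fx$z), 2, seed = 2)
  expect_equal(adjusted_rand_index(labs, fx$labels), 1)
})

test_that("sum-of-squares decomposition is exact and bounded", {
  set.seed(9)
  v <- matrix(rnorm(200), 50, 4)
  labs <- sample(1:3, 50, replace = TRUE)
  ss <- schae:::ss_decompose(v, labs)
  expect_equal(ss[["between"]] + ss[["within"]], ss[["total"]],
               tolerance = 1e-8)
  # one cluster: nothing between; singletons: nothing within
  expect_equal(schae:::ss_decompose(v, rep(1, 50))[["between"]], 0,
               tolerance = 1e-10)
  expect_equal(schae:::ss_decompose(v, 1:50)[["within"]], 0)
})

test_that("index scan satisfies the SS identity at every candidate k", {
  fx <- make_profile_blobs(30, list(c(2, 0, 0), c(0, 2, 0), c(0, 0, 2)),
                           sd = 0.4, seed = 3)
  scan <- cluster_index_scan(fx$z, j_range = 2:6, seed = 1)
  expect_equal(scan$ss_between + scan$ss_within, scan$ss_total,
               tolerance = 1e-8)
  expect_true(all(scan$index1 >= 0 & scan$index1 <= 1))
})

test_that("the cluster number of crisp blob data is predicted correctly", {
  fx <- make_profile_blobs(
    50, list(c(3, 0, 0, 0), c(0, 3, 0, 0), c(0, 0, 3, 0), c(0, 0, 0, 3)),
    sd = 0.3, seed = 8)
  k <- predict_n_clusters(fx$z, seed = 2)
  expect_equal(as.integer(k), 4L)
})

test_that("wMetaC consensus respects agreement and improves noisy replicates", {
  base <- rep(1:4, each = 50)
  # identical partitions under permuted label names collapse to themselves
  reps <- list(base, c(2L, 3L, 4L, 1L)[base], c(4L, 1L, 2L, 3L)[base])
  expect_equal(adjusted_rand_index(consensus_wmetac(reps), base), 1)

  # noisy perturbations: consensus at least as good as the best replicate
  set.seed(13)
  noisy <- lapply(1:10, function(i) {
    lab <- base
    flip <- sample(200, 10)
    lab[flip] <- sample(1:4, 10, replace = TRUE)
    lab
  })
  cons <- consensus_wmetac(noisy, k = 4)
  aris <- vapply(noisy, function(l) adjusted_rand_index(l, base), 1)
  expect_gte(adjusted_rand_index(cons, base), max(aris) - 0.02)

  # relabeling a replicate leaves the consensus partition unchanged
  relabeled <- noisy
  relabeled[[1]] <- c(3L, 4L, 1L, 2L)[relabeled[[1]]]
  expect_equal(adjusted_rand_index(consensus_wmetac(relabeled, k = 4), cons), 1)

  expect_error(consensus_wmetac(list(1:4, 1:5)), "unequal")
})

test_that("voting keeps core labels and recovers held-out duplicates", {
  fx <- make_profile_blobs(30, list(c(2, 0, 0), c(0, 2, 0)), sd = 0.3, seed = 4)
  z <- fx$z
  core <- seq_len(nrow(z))
  expect_identical(vote_assign(fx$labels, z, core), fx$labels)

  # held-out exact duplicate inherits its twin's label
  z2 <- rbind(z, z[1, , drop = FALSE])
  out <- vote_assign(fx$labels, z2, core, k_vote = 1)
  expect_identical(out[nrow(z2)], fx$labels[1])
  expect_error(vote_assign(integer(0), z, integer(0)), "empty")
})

test_that("a single replicate pipeline equals one spectral run", {
  sim <- simulate_cells(n_cells = 150, n_genes = 300, n_groups = 3, seed = 21)
  x <- suppressMessages(preprocess_matrix(sim$counts))
  res <- suppressMessages(
    cluster_cells(x, n_replicates = 1, k = 3, seed = 5,
                  vae_args = tiny_vae_args))
  rseed <- schae:::derive_seed(5, 1)
  v <- do.call(train_stacked_vae, c(list(x = x, seed = rseed), tiny_vae_args))
  z <- encode_cells(v, x)
  manual <- knn_spectral_cluster(build_knn_affinity(z), 3, seed = rseed)
  expect_equal(adjusted_rand_index(res$labels, manual), 1)
  expect_identical(res$k, 3L)
  expect_true(all(sort(unique(res$labels)) == seq_len(max(res$labels))))
})
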