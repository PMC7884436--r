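make_grouped_scaled <- function(n = 300, g = 600, k = 5, seed = 11) {
  sim <- simulate_cells(n_cells = n, n_genes = g, n_groups = k, seed = seed)
  list(x = suppressMessages(preprocess_matrix(sim$counts)),
       labels = sim$labels)
}

test_that("reparameterization is mu + sigma * eps with gradient pass-through", {
  expect_equal(reparameterize(c(1, 2), c(0, 0), c(5, -5)), c(1, 2))
  expect_error(reparameterize(1:3, 1:2, 1:3), "equal lengths")
  expect_error(reparameterize(c(0, 0), c(-1, 1), c(0, 0)), "non-negative")

  set.seed(1)
  eps <- rnorm(1e5)
  z <- reparameterize(rep(0, 1e5), rep(1, 1e5), eps)
  expect_lt(abs(mean(z)), 3 / sqrt(1e5))
  expect_lt(abs(var(z) - 1), 3 * sqrt(2 / 1e5))

  # finite-difference gradient through the sample
  h <- 1e-6
  mu <- 0.3; sig <- 0.7; e <- -1.2
  expect_equal((reparameterize(mu + h, sig, e) - reparameterize(mu - h, sig, e)) / (2 * h),
               1, tolerance = 1e-6)
  expect_equal((reparameterize(mu, sig + h, e) - reparameterize(mu, sig - h, e)) / (2 * h),
               e, tolerance = 1e-6)
})

test_that("training is deterministic and two-stage losses behave", {
  fx <- make_grouped_scaled(80, 60, 3, seed = 2)
  v1 <- do.call(train_stacked_vae, c(list(x = fx$x, m = 4, seed = 7), tiny_vae_args))
  v2 <- do.call(train_stacked_vae, c(list(x = fx$x, m = 4, seed = 7), tiny_vae_args))
  expect_identical(encode_cells(v1, fx$x), encode_cells(v2, fx$x))

  # warm-up epochs carry no KL penalty; stage 2 does
  expect_true(all(v1$kl_trace[seq_len(tiny_vae_args$warmup_epochs)] == 0))
  expect_true(all(v1$kl_trace[-seq_len(tiny_vae_args$warmup_epochs)] > 0))
  expect_lt(tail(v1$recon_trace, 1), v1$recon_trace[1])

  # warmup == epochs reduces to a pure autoencoder (KL never applied)
  v3 <- train_stacked_vae(fx$x, m = 4, epochs = 4, warmup_epochs = 4,
                          n_realizations = 1, seed = 7)
  expect_true(all(v3$kl_trace == 0))
})

test_that("posterior KL of a trained model is finite and non-negative", {
  fx <- make_grouped_scaled(60, 50, 2, seed = 3)
  v <- do.call(train_stacked_vae, c(list(x = fx$x, m = 3, seed = 1), tiny_vae_args))
  kl <- posterior_kl(v, fx$x)
  expect_true(is.finite(kl))
  expect_gte(kl, 0)
})

test_that("encoding is deterministic, shape-correct, and checks gene sets", {
  fx <- make_grouped_scaled(50, 40, 2, seed = 4)
  v <- do.call(train_stacked_vae, c(list(x = fx$x, m = 6, seed = 5), tiny_vae_args))
  z <- encode_cells(v, fx$x)
  expect_identical(dim(z), c(50L, 6L))
  expect_identical(encode_cells(v, fx$x), z)
  expect_identical(dim(encode_cells(v, fx$x[1, , drop = FALSE])), c(1L, 6L))

  wrong <- fx$x[, 1:30]
  expect_error(encode_cells(v, wrong), "gene")
})

# shared five-group fixture, compressed at three latent widths (trained once)
grouped_fx <- make_grouped_scaled(600, 1000, 5, seed = 11)
grouped_z <- lapply(c(m10 = 10L, m15 = 15L, m20 = 20L), function(mm) {
  v <- train_stacked_vae(grouped_fx$x, m = mm, seed = 3)
  encode_cells(v, grouped_fx$x)
})

test_that("compression sharpens group structure relative to the scaled matrix", {
  sil <- function(mat) {
    mean(cluster::silhouette(grouped_fx$labels, dist(mat))[, 3])
  }
  expect_gt(sil(grouped_z$m15), sil(grouped_fx$x))
})

test_that("latent dimensionality in 10..20 gives equivalent clusterings", {
  ari <- vapply(grouped_z, function(z) {
    labs <- knn_spectral_cluster(build_knn_affinity(z), 5, seed = 3)
    adjusted_rand_index(labs, grouped_fx$labels)
  }, 1)
  expect_true(all(abs(ari - ari[["m15"]]) <= 0.05))
})
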