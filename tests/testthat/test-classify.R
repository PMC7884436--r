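test_that("gene alignment intersects and canonicalizes column order", {
  m1 <- matrix(rpois(12, 4), 3, 4,
               dimnames = list(paste0("a", 1:3), c("A", "B", "C", "D")))
  m2 <- matrix(rpois(12, 4), 3, 4,
               dimnames = list(paste0("b", 1:3), c("B", "C", "D", "E")))
  al <- align_common_genes(m1, m2)
  expect_identical(colnames(al$train), c("B", "C", "D"))
  expect_identical(colnames(al$train), colnames(al$test))

  m3 <- m2; colnames(m3) <- c("X", "Y", "Z", "W")
  expect_error(align_common_genes(m1, m3), "no common genes")

  al_same <- align_common_genes(m1, m1)
  expect_identical(al_same$train, m1)
})

test_that("a duplicated test set is labelled perfectly at k = 1", {
  sim <- simulate_cells(n_cells = 120, n_genes = 300, n_groups = 3, seed = 31)
  test <- sim$counts
  rownames(test) <- paste0("copy_", rownames(test))
  res <- classify_cells(sim$counts, sim$labels, test, k = 1, seed = 2,
                        vae_args = tiny_vae_args, fs_args = tiny_fs_args)
  expect_identical(res$predicted_label, as.character(sim$labels))
  expect_true(all(res$vote_fraction == 1))
})

test_that("a single training class propagates to every test cell", {
  sim <- simulate_cells(n_cells = 60, n_genes = 200, n_groups = 2, seed = 32)
  res <- classify_cells(sim$counts, rep("only", 60), sim$counts * 2, k = 5,
                        seed = 3, vae_args = tiny_vae_args,
                        fs_args = tiny_fs_args)
  expect_true(all(res$predicted_label == "only"))
})

test_that("per-cell normalization makes the pipeline scale invariant", {
  # low-expression fixture: the global range stays under the log-transform
  # threshold for both the raw and the rescaled matrix, so min-max is the
  # only active normalization and cancels the per-cell scale exactly
  # (up to floating-point round-off)
  sim <- simulate_cells(n_cells = 100, n_genes = 250, n_groups = 3,
                        mean_rate = 2, dropout_target = NULL, seed = 33)
  test <- simulate_cells(n_cells = 50, n_genes = 250, n_groups = 3,
                         mean_rate = 2, dropout_target = NULL, seed = 34)$counts
  set.seed(35)
  scaled <- test * rep(runif(nrow(test), 0.5, 1.5), ncol(test))
  expect_lt(max(scaled) - min(scaled), 100)
  expect_equal(suppressMessages(preprocess_matrix(scaled)),
               suppressMessages(preprocess_matrix(test)),
               tolerance = 1e-12, ignore_attr = TRUE)

  # round-off seeds tiny training differences, so downstream labels are
  # compared in aggregate rather than cell-by-cell
  r1 <- classify_cells(sim$counts, sim$labels, test, k = 5, seed = 4,
                       vae_args = tiny_vae_args, fs_args = tiny_fs_args)
  r2 <- classify_cells(sim$counts, sim$labels, scaled, k = 5, seed = 4,
                       vae_args = tiny_vae_args, fs_args = tiny_fs_args)
  expect_gte(mean(r1$predicted_label == r2$predicted_label), 0.9)
})

test_that("k larger than the training set is rejected", {
  sim <- simulate_cells(n_cells = 20, n_genes = 100, seed = 35)
  expect_error(
    classify_cells(sim$counts, sim$labels, sim$counts, k = 25, seed = 1),
    "exceeds")
})
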