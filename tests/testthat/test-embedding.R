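test_that("standardized log distances have zero-mean unit-sd rows", {
  set.seed(1)
  z <- matrix(rnorm(15 * 6), 15, 6)
  d <- transform_distances(z)
  for (i in 1:15) {
    expect_lt(abs(mean(d[i, -i])), 1e-6)
    expect_lt(abs(sd(d[i, -i]) - 1), 1e-6)
  }
  expect_equal(diag(d), rep(0, 15))
})

test_that("equidistant cells standardize to zero and order is preserved", {
  # three mutually equidistant cells: zero spread rows map to zero
  z <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  expect_true(all(transform_distances(z) == 0))

  set.seed(2)
  z <- matrix(rnorm(60), 10, 6)
  raw <- 1 - cor(t(z))
  std <- transform_distances(z)
  for (i in 1:10) {
    expect_identical(order(std[i, -i]), order(raw[i, -i]))
  }
})

test_that("neighbour probabilities are normalized, symmetric, similarity-ordered", {
  set.seed(3)
  z <- matrix(rnorm(12 * 5), 12, 5)
  d <- transform_distances(z)
  p <- neighbor_probabilities(d)
  pc <- attr(p, "conditional")
  expect_equal(rowSums(pc), rep(1, 12), tolerance = 1e-12)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_equal(p, t(p), tolerance = 1e-15, ignore_attr = TRUE)
  expect_equal(diag(p), rep(0, 12))
  for (i in 1:12) {
    expect_equal(which.max(pc[i, ]), which.min(replace(d[i, ], i, Inf)))
  }
})

test_that("KL divergence matches direct summation and Gibbs' inequality", {
  expect_equal(kl_divergence(matrix(0.25, 2, 2), matrix(0.25, 2, 2)), 0)
  for (i in 1:5) {
    set.seed(i)
    n <- sample(5:20, 1)
    z1 <- matrix(rnorm(n * 4), n, 4)
    z2 <- matrix(rnorm(n * 4), n, 4)
    p <- neighbor_probabilities(transform_distances(z1))
    q <- neighbor_probabilities(transform_distances(z2))
    expect_gte(kl_divergence(p, q), 0)
    expect_equal(kl_divergence(p, q), oracle_kl(p, q), tolerance = 1e-10)
  }
})

test_that("analytic coordinate gradient matches finite differences", {
  set.seed(4)
  n <- 8
  z <- matrix(rnorm(n * 5), n, 5)
  p <- neighbor_probabilities(transform_distances(z))
  y <- matrix(rnorm(n * 2), n, 2)
  qq <- schae:::q_from_coords(y)
  g <- schae:::kl_coord_gradient(p, qq$conditional, y, qq$d)
  h <- 1e-6
  f <- function(yy) kl_divergence(p, schae:::q_from_coords(yy)$joint)
  for (i in c(1, 4, 8)) for (j in 1:2) {
    yp <- y; yp[i, j] <- yp[i, j] + h
    ym <- y; ym[i, j] <- ym[i, j] - h
    expect_equal(unname(g[i, j]), (f(yp) - f(ym)) / (2 * h),
                 tolerance = 1e-5)
  }
})

test_that("rigid motions of the 2D coordinates leave Q and KL unchanged", {
  set.seed(5)
  y <- matrix(rnorm(20), 10, 2)
  theta <- 0.7
  rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  y2 <- y %*% rot + rep(c(3, -1), each = 10)
  q1 <- schae:::q_from_coords(y)$joint
  q2 <- schae:::q_from_coords(y2)$joint
  expect_equal(q1, q2, tolerance = 1e-9)
})

test_that("embedding training reduces KL and is equivariant to cell order", {
  set.seed(6)
  fx <- make_profile_blobs(20, list(c(2, 0, 0, 0), c(0, 0, 2, 0)), sd = 0.4,
                           seed = 6)
  emb <- fit_embedding(fx$z, epochs = 30, seed = 1)
  expect_true(all(is.finite(emb$coords)))
  expect_lte(emb$final_kl, emb$kl_trace[1])
  expect_true(all(diff(emb$kl_trace) <= 1e-12))

  perm <- sample(nrow(fx$z))
  emb_p <- fit_embedding(fx$z[perm, ], epochs = 5, seed = 1)
  emb_o <- fit_embedding(fx$z, epochs = 5, seed = 1)
  expect_equal(emb_p$coords, emb_o$coords[perm, ], tolerance = 1e-6,
               ignore_attr = TRUE)
})
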