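# Two-dimensional visualization: neighbourhood probabilities are derived
# from row-standardized log distances, and a small SELU network is trained
# to place cells in 2D so that the low-dimensional neighbourhood
# distribution Q matches the high-dimensional P in Kullback-Leibler
# divergence. The same transform chain (log -> row z-score -> softmax of
# negated values -> symmetrization) produces both P and Q; only the distance
# metric differs (Pearson distance in latent space, Euclidean in 2D, where
# Pearson correlation between 2-vectors is degenerate).

.dist_floor <- 1e-12

pearson_distance <- function(z) {
  d <- 1 - row_cor(z)
  d[d < 0] <- 0  # round-off guard
  d
}

euclidean_distance <- function(y) {
  as.matrix(stats::dist(y))
}

# Row-wise z-scored log distances; diagonal fixed at 0 and excluded from
# the statistics. Zero distances are floored with a warning upstream.
standardize_log_dist <- function(d, warn_zero = TRUE) {
  n <- nrow(d)
  if (n < 3L) stop("need at least 3 cells", call. = FALSE)
  off <- d[upper.tri(d) | lower.tri(d)]
  if (any(off <= 0) && warn_zero) {
    warning("zero pairwise distances floored at 1e-12 (duplicate cells?)")
  }
  d[d < .dist_floor] <- .dist_floor
  lt <- log(d)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) {
    row <- lt[i, -i]
    s <- stats::sd(row)
    out[i, -i] <- if (s > 0) (row - mean(row)) / s else 0
  }
  out
}

#' Row-standardized log distance matrix of the compressed cells
#'
#' Computes the Pearson distance matrix (`1 - r`) of the latent vectors,
#' then log-transforms and z-scores each row over its off-diagonal entries:
#' `D_ij = (log D_ij - mean_i) / sd_i`. The transform flattens each cell's
#' distance profile so that near and far neighbours contribute on a common
#' scale.
#'
#' @param z compressed matrix (cells x latent dims), at least 3 cells.
#' @return cells x cells matrix; each off-diagonal row has mean 0 and sd 1
#'   (rows with zero spread are mapped to 0); diagonal is 0.
#' @export
transform_distances <- function(z) {
  standardize_log_dist(pearson_distance(z))
}

# Conditional + symmetrized neighbourhood probabilities from a standardized
# distance matrix. Nearer cells (more negative standardized distance) get
# larger probability via softmax of -D.
probs_from_standardized <- function(dz) {
  n <- nrow(dz)
  logits <- -dz
  diag(logits) <- -Inf
  mx <- apply(logits, 1L, max)
  e <- exp(logits - mx)
  diag(e) <- 0
  pc <- e / rowSums(e)
  p <- (pc + t(pc)) / (2 * n)
  list(conditional = pc, joint = p)
}

#' Symmetrized neighbourhood probabilities of the compressed cells
#'
#' Conditional probabilities `p_{j|i} = exp(-D_ij) / sum_{k != i}
#' exp(-D_ik)` are computed from the standardized distances (the negative
#' sign makes probability proportional to similarity), then symmetrized to
#' the joint distribution `p_ij = (p_{j|i} + p_{i|j}) / (2n)`, which sums
#' to 1 over all ordered pairs with zero diagonal.
#'
#' @param dz standardized distance matrix from [transform_distances()].
#' @return cells x cells symmetric matrix summing to 1, zero diagonal; the
#'   conditional matrix is attached as attribute `conditional`.
#' @export
neighbor_probabilities <- function(dz) {
  pr <- probs_from_standardized(dz)
  structure(pr$joint, conditional = pr$conditional)
}

#' Kullback-Leibler divergence between two neighbourhood distributions
#'
#' `KL(P || Q) = sum_{i != j} p_ij log(p_ij / q_ij)`; terms with
#' `p_ij = 0` contribute zero, and `q` is floored at `1e-12` for numerical
#' safety.
#'
#' @param p,q matching non-negative matrices (joint neighbourhood
#'   probabilities).
#' @return non-negative scalar.
#' @export
kl_divergence <- function(p, q) {
  pos <- p > 0
  sum(p[pos] * log(p[pos] / pmax(q[pos], 1e-12)))
}

# Probabilities from 2D coordinates: Euclidean distances through the same
# standardization chain. Returns caches for backpropagation.
q_from_coords <- function(y) {
  d <- euclidean_distance(y)
  d[d < .dist_floor] <- .dist_floor
  dz <- standardize_log_dist(d, warn_zero = FALSE)
  pr <- probs_from_standardized(dz)
  list(d = d, dz = dz, conditional = pr$conditional, joint = pr$joint)
}

# Analytic gradient of KL(P||Q) with respect to the 2D coordinates,
# backpropagated through: joint symmetrization <- row softmax <- row
# z-score <- log <- Euclidean distance.
kl_coord_gradient <- function(p, qc, y, d, lt_cache = NULL) {
  n <- nrow(y)
  q <- (qc + t(qc)) / (2 * n)
  gq <- -p / pmax(q, 1e-12)          # dKL/dq_ij
  gpc <- (gq + t(gq)) / (2 * n)      # dKL/dpc_ij (q symmetric in pc, pc^T)
  # softmax rows with logits -Dz: dL_ij = pc_ij * (g_ij - sum_k g_ik pc_ik)
  rs <- rowSums(gpc * qc)
  glogit <- qc * (gpc - rs)
  gdz <- -glogit
  # z-score backward per row
  lt <- log(d)
  gt <- matrix(0, n, n)
  for (i in seq_len(n)) {
    xr <- lt[i, -i]
    s <- stats::sd(xr)
    if (s == 0) next
    yr <- (xr - mean(xr)) / s
    dy <- gdz[i, -i]
    nn <- length(xr)
    gt[i, -i] <- (dy - mean(dy) - yr * sum(dy * yr) / (nn - 1)) / s
  }
  gd <- gt / d
  gd_sym <- gd + t(gd)               # d_ij appears in rows i and j
  cmat <- gd_sym / d
  diag(cmat) <- 0
  rowSums(cmat) * y - cmat %*% y     # sum_j C_ij (y_i - y_j)
}

#' Learn a 2D embedding of the compressed cells
#'
#' Trains a small projection network (`latent -> 32 SELU -> 2`) with AdamW
#' so that the 2D neighbourhood distribution `Q` (recomputed from the
#' coordinates every epoch with the same log/z-score/softmax chain as `P`)
#' stays close to the latent-space distribution `P` in Kullback-Leibler
#' divergence.
#'
#' @param z compressed matrix (cells x latent dims).
#' @param epochs full-batch training epochs (default 100).
#' @param hidden hidden width of the projection network (default 32).
#' @param lr,weight_decay AdamW hyperparameters; the learning rate decays
#'   linearly to 10% of `lr` over training, which settles the late-epoch
#'   KL descent.
#' @param dims output dimensionality (default 2; the chain generalizes).
#' @param seed RNG seed for initialization.
#' @return object of class `embedding2d`: list with `coords` (cells x
#'   `dims`, row names from `z`), `final_kl`, and the per-epoch `kl_trace`.
#' @export
fit_embedding <- function(z, epochs = 100L, hidden = 32L, lr = 1e-2,
                          weight_decay = 1e-2, dims = 2L, seed = 1L) {
  stopifnot(is.matrix(z), nrow(z) >= 3L)
  n <- nrow(z); m <- ncol(z)
  set.seed(seed)
  p <- neighbor_probabilities(transform_distances(z))

  params <- list(
    W1 = init_weight(m, hidden), b1 = numeric(hidden),
    W2 = init_weight(hidden, dims), b2 = numeric(dims)
  )
  opt <- adamw_init(params, lr = lr, weight_decay = weight_decay)
  kl_trace <- numeric(epochs)
  coords <- NULL
  lr_scale <- 1
  prev <- NULL  # last accepted (params, opt) for the monotone safeguard
  for (ep in seq_len(epochs)) {
    fwd <- function(pa) {
      pre1 <- z %*% pa$W1 + rep(pa$b1, each = n)
      h <- selu(pre1)
      y <- h %*% pa$W2 + rep(pa$b2, each = n)
      list(pre1 = pre1, h = h, y = y, q = q_from_coords(y))
    }
    f <- fwd(params)
    kl <- kl_divergence(p, f$q$joint)
    if (!is.finite(kl)) stop("embedding diverged (non-finite KL)", call. = FALSE)
    # monotone safeguard: a step that raised the KL is rejected and retried
    # from the previous state with half the step size
    if (ep > 1L && kl > kl_trace[ep - 1L]) {
      params <- prev$params; opt <- prev$opt
      lr_scale <- lr_scale / 2
      f <- fwd(params)
      kl <- kl_trace[ep - 1L]
    } else if (ep > 1L) {
      lr_scale <- min(1, lr_scale * 1.2)  # recover step size after acceptance
    }
    kl_trace[ep] <- kl
    prev <- list(params = params, opt = opt)
    coords <- f$y
    opt$lr <- lr * lr_scale * (1 - 0.9 * (ep - 1) / max(epochs - 1, 1))
    gy <- kl_coord_gradient(p, f$q$conditional, f$y, f$q$d)
    gh <- gy %*% t(params$W2)
    gpre1 <- gh * selu_grad(f$pre1)
    grads <- list(
      W1 = crossprod(z, gpre1), b1 = colSums(gpre1),
      W2 = crossprod(f$h, gy), b2 = colSums(gy)
    )
    st <- adamw_step(params, grads, opt)
    params <- st$params; opt <- st$state
  }
  final <- kl_divergence(p, q_from_coords(coords)$joint)
  rownames(coords) <- rownames(z)
  colnames(coords) <- paste0("dim", seq_len(dims))
  structure(list(coords = coords, final_kl = final, kl_trace = kl_trace,
                 seed = seed),
            class = "embedding2d")
}
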