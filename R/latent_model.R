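# Stacked Bayesian autoencoder: a variational autoencoder whose
# reconstruction term averages over several stochastic realizations of the
# latent code z = mu + sigma * eps, trained in two stages (reconstruction-only
# warm-up, then reconstruction + KL toward N(0, I)). All gradients are
# derived analytically and computed with dense matrix algebra.

.sigma_min <- 1e-4
.sigma_max <- 10

#' Reparameterization of a diagonal Gaussian
#'
#' Computes `z = mu + sigma * eps` elementwise, the differentiable sampling
#' trick that lets gradients flow to `mu` and `sigma` through a stochastic
#' latent code.
#'
#' @param mu mean vector (or matrix).
#' @param sigma standard deviation, same length/shape as `mu`, elementwise
#'   non-negative.
#' @param eps standard-normal draw, same length/shape.
#' @return `mu + sigma * eps`.
#' @export
reparameterize <- function(mu, sigma, eps) {
  if (length(mu) != length(sigma) || length(mu) != length(eps)) {
    stop("mu, sigma and eps must have equal lengths", call. = FALSE)
  }
  if (any(sigma < 0)) stop("sigma must be elementwise non-negative", call. = FALSE)
  mu + sigma * eps
}

vae_init_params <- function(g, hidden, m, sigma_init = 0.1) {
  list(
    W1 = init_weight(g, hidden), b1 = numeric(hidden),
    Wm = init_weight(hidden, m), bm = numeric(m),
    # the log-sigma head starts near log(sigma_init): a small initial
    # posterior sd keeps the reconstruction signal visible through z from
    # the first epochs instead of drowning it in unit-variance noise
    Ws = init_weight(hidden, m) * 0.1, bs = rep(log(sigma_init), m),
    W3 = init_weight(m, hidden), b3 = numeric(hidden),
    W4 = init_weight(hidden, g), b4 = numeric(g)
  )
}

# Forward pass through the encoder only; returns mu, sigma and the caches
# needed for backpropagation. sigma = exp(log-sigma head) clipped to
# [.sigma_min, .sigma_max]; gradients are gated to zero where the clip binds.
vae_encode_forward <- function(params, xb) {
  b <- nrow(xb)
  pre1 <- xb %*% params$W1 + rep(params$b1, each = b)
  h <- selu(pre1)
  mu <- h %*% params$Wm + rep(params$bm, each = b)
  logsig <- h %*% params$Ws + rep(params$bs, each = b)
  sig_raw <- exp(logsig)
  sigma <- pmin(pmax(sig_raw, .sigma_min), .sigma_max)
  list(pre1 = pre1, h = h, mu = mu, logsig = logsig,
       sigma = sigma, clip_free = (sig_raw > .sigma_min & sig_raw < .sigma_max))
}

#' Train the stacked Bayesian autoencoder
#'
#' Compresses a gene-filtered scaled matrix to an `m`-dimensional latent
#' space. Architecture: one SELU hidden layer (`x -> hidden -> (mu, sigma)`)
#' and a mirrored SELU decoder shared across realizations. Per minibatch the
#' reconstruction loss (sum of squared error over genes, averaged over cells)
#' is averaged over `n_realizations` independent draws
#' `z = mu + sigma * eps`. Training is two-stage: `warmup_epochs` of
#' reconstruction-only optimization, then the remaining epochs add the
#' analytic KL divergence of `N(mu, sigma^2)` from `N(0, I)`. AdamW is the
#' optimizer throughout.
#'
#' @param x scaled, gene-filtered matrix (cells x genes, values in `[0,1]`).
#' @param m latent dimensionality (default 15).
#' @param hidden hidden-layer width (default 64).
#' @param warmup_epochs reconstruction-only epochs (default 20).
#' @param epochs total epochs (default 60); must be >= `warmup_epochs`.
#' @param n_realizations draws of `z` averaged per forward pass (default 5);
#'   with 1 the objective is a standard VAE.
#' @param batch_size minibatch size; default `min(n_cells, 32)` — small
#'   batches buy the optimizer enough steps to learn cell-type structure,
#'   not just gene means.
#' @param lr,weight_decay AdamW hyperparameters (defaults 5e-3 and 1e-2).
#' @param kl_weight weight of the KL term in stage 2 (default 1).
#' @param sigma_init initial posterior standard deviation (default 0.1);
#'   the log-sigma head's bias starts at `log(sigma_init)`.
#' @param seed RNG seed; identical `(x, seed)` reproduce identical weights.
#' @return object of class `stacked_vae` with the weight list, training
#'   metadata, per-epoch loss traces (`recon_trace`, `kl_trace`), and the
#'   training gene identifiers.
#' @export
train_stacked_vae <- function(x, m = 15L, hidden = 64L, warmup_epochs = 20L,
                              epochs = 60L, n_realizations = 5L,
                              batch_size = NULL, lr = 5e-3,
                              weight_decay = 1e-2, kl_weight = 1,
                              sigma_init = 0.1, seed = 1L) {
  validate_expression_matrix(x)
  n <- nrow(x); g <- ncol(x)
  m <- as.integer(m); hidden <- as.integer(hidden)
  epochs <- as.integer(epochs); warmup_epochs <- as.integer(warmup_epochs)
  if (epochs < warmup_epochs) stop("epochs must be >= warmup_epochs", call. = FALSE)
  if (is.null(batch_size)) batch_size <- min(n, 32L)
  R <- as.integer(n_realizations)
  set.seed(seed)

  params <- vae_init_params(g, hidden, m, sigma_init = sigma_init)
  opt <- adamw_init(params, lr = lr, weight_decay = weight_decay)
  recon_trace <- numeric(epochs); kl_trace <- numeric(epochs)

  for (ep in seq_len(epochs)) {
    stage2 <- ep > warmup_epochs
    batches <- epoch_batches(n, batch_size)
    ep_recon <- 0; ep_kl <- 0
    for (idx in batches) {
      xb <- x[idx, , drop = FALSE]
      b <- nrow(xb)
      enc <- vae_encode_forward(params, xb)
      mu <- enc$mu; sigma <- enc$sigma

      d_mu <- matrix(0, b, m); d_sigma <- matrix(0, b, m)
      gW3 <- matrix(0, m, hidden); gb3 <- numeric(hidden)
      gW4 <- matrix(0, hidden, g); gb4 <- numeric(g)
      recon <- 0
      for (r in seq_len(R)) {
        eps <- matrix(stats::rnorm(b * m), b, m)
        z <- mu + sigma * eps
        pre2 <- z %*% params$W3 + rep(params$b3, each = b)
        h2 <- selu(pre2)
        xhat <- h2 %*% params$W4 + rep(params$b4, each = b)
        resid <- xhat - xb
        recon <- recon + sum(resid^2) / (b * R)
        d_xhat <- 2 * resid / (b * R)
        gW4 <- gW4 + crossprod(h2, d_xhat)
        gb4 <- gb4 + colSums(d_xhat)
        d_pre2 <- (d_xhat %*% t(params$W4)) * selu_grad(pre2)
        gW3 <- gW3 + crossprod(z, d_pre2)
        gb3 <- gb3 + colSums(d_pre2)
        d_z <- d_pre2 %*% t(params$W3)
        d_mu <- d_mu + d_z
        d_sigma <- d_sigma + d_z * eps
      }
      if (!is.finite(recon)) {
        stop(sprintf("training diverged (non-finite loss) at epoch %d, seed %d",
                     ep, seed), call. = FALSE)
      }
      kl <- 0
      if (stage2) {
        kl <- 0.5 * sum(mu^2 + sigma^2 - 1 - 2 * log(sigma)) / b
        d_mu <- d_mu + kl_weight * mu / b
        d_sigma <- d_sigma + kl_weight * (sigma - 1 / sigma) / b
      }
      ep_recon <- ep_recon + recon * b; ep_kl <- ep_kl + kl * b

      d_logsig <- d_sigma * sigma * enc$clip_free
      d_h <- d_mu %*% t(params$Wm) + d_logsig %*% t(params$Ws)
      d_pre1 <- d_h * selu_grad(enc$pre1)
      grads <- list(
        W1 = crossprod(xb, d_pre1), b1 = colSums(d_pre1),
        Wm = crossprod(enc$h, d_mu), bm = colSums(d_mu),
        Ws = crossprod(enc$h, d_logsig), bs = colSums(d_logsig),
        W3 = gW3, b3 = gb3, W4 = gW4, b4 = gb4
      )
      st <- adamw_step(params, grads, opt)
      params <- st$params; opt <- st$state
    }
    recon_trace[ep] <- ep_recon / n; kl_trace[ep] <- ep_kl / n
  }

  structure(list(
    params = params, m = m, hidden = hidden,
    n_realizations = R, warmup_epochs = warmup_epochs, epochs = epochs,
    gene_ids = colnames(x), n_genes = g,
    recon_trace = recon_trace, kl_trace = kl_trace, seed = seed
  ), class = "stacked_vae")
}

#' Encode cells into the latent space
#'
#' Deterministic inference: cells are pushed through the trained encoder and
#' the posterior mean `mu` is returned as the compressed representation (no
#' sampling at inference time, so every downstream analysis of a trained
#' model is reproducible).
#'
#' @param model a `stacked_vae` from [train_stacked_vae()].
#' @param x scaled matrix whose gene set matches the training gene set.
#' @return cells x `m` numeric matrix, row names carried over from `x`.
#' @export
encode_cells <- function(model, x) {
  stopifnot(inherits(model, "stacked_vae"))
  validate_expression_matrix(x)
  if (ncol(x) != model$n_genes) {
    stop(sprintf("gene set mismatch: model trained on %d genes, input has %d",
                 model$n_genes, ncol(x)), call. = FALSE)
  }
  if (!is.null(model$gene_ids) && !is.null(colnames(x))) {
    missing <- setdiff(model$gene_ids, colnames(x))
    if (length(missing)) {
      stop("input is missing training genes: ",
           paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
    }
    x <- x[, model$gene_ids, drop = FALSE]
  }
  enc <- vae_encode_forward(model$params, x)
  z <- enc$mu
  rownames(z) <- rownames(x)
  z
}

#' Analytic KL divergence of the encoder posterior from the prior
#'
#' Mean over cells of `KL(N(mu, sigma^2) || N(0, I))`; finite and
#' non-negative for any trained model.
#'
#' @inheritParams encode_cells
#' @return non-negative scalar.
#' @export
posterior_kl <- function(model, x) {
  stopifnot(inherits(model, "stacked_vae"))
  enc <- vae_encode_forward(model$params, x)
  0.5 * sum(enc$mu^2 + enc$sigma^2 - 1 - 2 * log(enc$sigma)) / nrow(x)
}
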