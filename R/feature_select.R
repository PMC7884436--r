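#' Train the one-layer non-negative kernel autoencoder
#'
#' Fits a linear autoencoder `x -> e = x W_E + b_E -> xhat = e W_D + b_D`
#' by minimizing mean-squared reconstruction error with AdamW. The encoder
#' weights `W_E` are constrained to be non-negative (clamped to zero after
#' every optimizer step), so each latent node is an additive, part-based
#' combination of genes; uninformative genes are shrunk toward zero weight
#' and can be recognized by the low variance of their encoder-weight row.
#'
#' @param x scaled matrix from [preprocess_matrix()] (cells x genes, values
#'   in `[0, 1]`).
#' @param latent_size bottleneck width (default 50).
#' @param epochs training epochs (default 100; the variance contrast between
#'   informative and background genes develops slowly).
#' @param batch_size minibatch size; default `min(n_cells, 32)`.
#' @param lr AdamW learning rate (default 1e-2).
#' @param weight_decay AdamW decoupled weight decay (default 0.1; the
#'   shrinkage is what drives uninformative encoder weights toward zero).
#' @param seed RNG seed controlling initialization and batch order; the same
#'   `(x, seed)` pair always yields identical weights.
#' @return object of class `nn_autoencoder`: list with `W_E` (genes x
#'   latent, non-negative), `b_E`, `W_D`, `b_D`, `loss_trace`, and metadata.
#' @export
train_nn_autoencoder <- function(x, latent_size = 50L, epochs = 100L,
                                 batch_size = NULL, lr = 1e-2,
                                 weight_decay = 0.1, seed = 1L) {
  validate_expression_matrix(x)
  n <- nrow(x); g <- ncol(x)
  if (n < 2L || g < 2L) stop("need at least 2 cells and 2 genes", call. = FALSE)
  latent_size <- as.integer(latent_size)
  if (is.null(batch_size)) batch_size <- min(n, 32L)
  set.seed(seed)

  params <- list(
    W_E = abs(init_weight(g, latent_size)),  # start inside the feasible cone
    b_E = numeric(latent_size),
    W_D = init_weight(latent_size, g),
    b_D = numeric(g)
  )
  opt <- adamw_init(params, lr = lr, weight_decay = weight_decay)

  loss_trace <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    batches <- epoch_batches(n, batch_size)
    ep_loss <- 0
    for (idx in batches) {
      xb <- x[idx, , drop = FALSE]
      b <- nrow(xb)
      e <- xb %*% params$W_E + rep(params$b_E, each = b)
      xhat <- e %*% params$W_D + rep(params$b_D, each = b)
      resid <- xhat - xb
      loss <- mean(resid^2)
      if (!is.finite(loss)) {
        stop(sprintf("training diverged (non-finite loss) at epoch %d, seed %d",
                     ep, seed), call. = FALSE)
      }
      ep_loss <- ep_loss + loss * b
      d_xhat <- 2 * resid / length(resid)
      grads <- list(
        W_E = crossprod(xb, d_xhat %*% t(params$W_D)),
        b_E = colSums(d_xhat %*% t(params$W_D)),
        W_D = crossprod(e, d_xhat),
        b_D = colSums(d_xhat)
      )
      st <- adamw_step(params, grads, opt)
      params <- st$params; opt <- st$state
      # non-negativity is enforced after *every* step, not only at the end
      params$W_E[params$W_E < 0] <- 0
    }
    loss_trace[ep] <- ep_loss / n
  }

  structure(list(
    W_E = params$W_E, b_E = as.numeric(params$b_E),
    W_D = params$W_D, b_D = as.numeric(params$b_D),
    latent_size = latent_size, gene_ids = colnames(x),
    loss_trace = loss_trace, seed = seed
  ), class = "nn_autoencoder")
}

#' Score genes by encoder-weight variance
#'
#' Computes, for each gene, the population variance (divide by
#' `latent_size`) of its row of the non-negative encoder weight matrix.
#' Genes whose weights are uniformly small (or uniformly anything) score
#' near zero; genes that load strongly on some latent parts but not others
#' score high and are the informative ones.
#'
#' @param model a trained [train_nn_autoencoder()] model.
#' @return numeric vector of non-negative scores, one per gene, named by
#'   gene when the training matrix carried gene names.
#' @export
score_genes <- function(model) {
  stopifnot(inherits(model, "nn_autoencoder"))
  w <- model$W_E
  sc <- rowMeans(w^2) - rowMeans(w)^2
  sc[sc < 0] <- 0  # guard tiny negative round-off
  names(sc) <- model$gene_ids
  sc
}

#' Pick the top-scoring genes
#'
#' Returns the selection object holding per-gene scores and the indices of
#' the `n_keep` highest-scoring genes (ties broken toward the lower gene
#' index, so the selection is deterministic).
#'
#' @param scores numeric vector from [score_genes()].
#' @param n_keep number of genes to retain (default 5000); capped at the
#'   number of genes available.
#' @return object of class `gene_selection`: list with `scores`,
#'   `kept_indices` (increasing order), `n_keep`.
#' @export
rank_gene_selection <- function(scores, n_keep = 5000L) {
  stopifnot(is.numeric(scores), length(scores) >= 1L, all(scores >= 0))
  n_keep <- min(as.integer(n_keep), length(scores))
  if (n_keep < 1L) stop("empty gene selection", call. = FALSE)
  ord <- order(-scores, seq_along(scores))
  kept <- sort(ord[seq_len(n_keep)])
  structure(list(scores = scores, kept_indices = kept, n_keep = n_keep),
            class = "gene_selection")
}

#' Subset a matrix to the selected genes
#'
#' @param x scaled matrix (cells x genes).
#' @param sel a `gene_selection` from [rank_gene_selection()].
#' @return `x` restricted to the kept gene columns; row order and cell
#'   names preserved.
#' @export
select_genes <- function(x, sel) {
  stopifnot(inherits(sel, "gene_selection"))
  if (length(sel$kept_indices) == 0L) stop("empty gene selection", call. = FALSE)
  if (max(sel$kept_indices) > ncol(x)) {
    stop("gene selection indices exceed matrix dimensions", call. = FALSE)
  }
  x[, sel$kept_indices, drop = FALSE]
}

#' Filter genes with the non-negative kernel autoencoder
#'
#' One-call convenience: train the non-negative autoencoder, score genes by
#' encoder-weight variance, and keep the top `n_keep` (default 5000).
#'
#' @inheritParams train_nn_autoencoder
#' @inheritParams rank_gene_selection
#' @param ... passed through to [train_nn_autoencoder()].
#' @return list with `matrix` (the filtered scaled matrix), `selection`
#'   (the `gene_selection`), and `model`.
#' @export
select_features <- function(x, n_keep = 5000L, latent_size = 50L, seed = 1L, ...) {
  model <- train_nn_autoencoder(x, latent_size = latent_size, seed = seed, ...)
  sel <- rank_gene_selection(score_genes(model), n_keep = n_keep)
  list(matrix = select_genes(x, sel), selection = sel, model = model)
}
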