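#' Restrict two expression matrices to their common genes
#'
#' Intersects the gene identifiers of a training and a testing matrix
#' (exact string match) and returns both restricted to the shared genes in
#' a single canonical order (the training matrix's order).
#'
#' @param train,test expression matrices (cells x genes) with gene column
#'   names.
#' @return list with elements `train` and `test`, both subset to the
#'   common genes in identical column order.
#' @export
align_common_genes <- function(train, test) {
  validate_expression_matrix(train, require_names = TRUE)
  validate_expression_matrix(test, require_names = TRUE)
  common <- intersect(colnames(train), colnames(test))
  if (length(common) == 0L) {
    stop("no common genes between data sets (train e.g. ",
         paste(utils::head(colnames(train), 3), collapse = ", "),
         "; test e.g. ",
         paste(utils::head(colnames(test), 3), collapse = ", "), ")",
         call. = FALSE)
  }
  list(train = train[, common, drop = FALSE],
       test = test[, common, drop = FALSE])
}

#' Transductive cell-type classification
#'
#' Implements the concatenate-compress-label procedure: (i) the training
#' and testing matrices are row-concatenated on their common genes; (ii)
#' the merged matrix is normalized, gene-filtered and compressed by the
#' hierarchical autoencoder exactly as in the unsupervised pipeline (labels
#' play no part in the embedding); (iii) Pearson similarity between test
#' and training cells is computed in the latent space; (iv) each test cell
#' receives the majority label of its `k` most similar training cells, with
#' ties resolved by the single most similar neighbour (optionally,
#' similarity-weighted votes).
#'
#' @param train expression matrix of the labelled cells.
#' @param labels cell-type labels of `train` rows (character or factor).
#' @param test expression matrix to label; gene sets are intersected with
#'   `train`.
#' @param k neighbours consulted (default 10); must not exceed the number
#'   of training cells.
#' @param n_keep genes retained by the feature-selection step
#'   (default 5000, capped at the common gene count).
#' @param weighted use similarity-weighted instead of unweighted votes.
#' @param seed master seed for the joint compression.
#' @param vae_args,fs_args extra arguments for [train_stacked_vae()] and
#'   [train_nn_autoencoder()].
#' @return data frame with `cell_id`, `predicted_label`, `vote_fraction`
#'   (fraction of the k votes won by the assigned label).
#' @export
classify_cells <- function(train, labels, test, k = 10L, n_keep = 5000L,
                           weighted = FALSE, seed = 1L,
                           vae_args = list(), fs_args = list()) {
  stopifnot(length(labels) == nrow(train))
  k <- as.integer(k)
  if (k > nrow(train)) stop("k exceeds the number of training cells", call. = FALSE)
  al <- align_common_genes(train, test)
  labels <- as.character(labels)

  merged <- rbind(al$train, al$test)
  rownames(merged) <- c(paste0("train:", rownames(al$train)),
                        paste0("test:", rownames(al$test)))
  x <- preprocess_matrix(merged)
  fs <- do.call(select_features,
                c(list(x = x, n_keep = min(n_keep, ncol(x)),
                       seed = derive_seed(seed, 1L)), fs_args))
  vae <- do.call(train_stacked_vae,
                 c(list(x = fs$matrix, seed = derive_seed(seed, 2L)), vae_args))
  z <- encode_cells(vae, fs$matrix)

  ntr <- nrow(al$train)
  z_tr <- z[seq_len(ntr), , drop = FALSE]
  z_te <- z[-seq_len(ntr), , drop = FALSE]
  sim <- row_cor(z_te, z_tr)

  pred <- character(nrow(z_te)); frac <- numeric(nrow(z_te))
  for (i in seq_len(nrow(z_te))) {
    nb <- order(sim[i, ], decreasing = TRUE)[seq_len(k)]
    wts <- if (weighted) pmax(sim[i, nb], 0) + 1e-12 else rep(1, k)
    tal <- tapply(wts, labels[nb], sum)
    top <- names(tal)[tal == max(tal)]
    pred[i] <- if (length(top) == 1L) top else labels[nb[1L]]
    frac[i] <- sum((labels[nb] == pred[i]) * wts) / sum(wts)
  }
  data.frame(cell_id = rownames(al$test), predicted_label = pred,
             vote_fraction = frac, stringsAsFactors = FALSE)
}
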