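# File I/O: dense CSV/TSV (header row = gene ids, first column = cell ids)
# and Matrix Market triplets with companion gene/barcode files; all outputs
# are plain TSV.

#' Read an expression matrix from disk
#'
#' Dense CSV/TSV files are expected to carry gene identifiers in the header
#' row and cell identifiers in the first column (use `cells_in_rows =
#' FALSE` for the transposed layout, which is auto-transposed). Matrix
#' Market (`.mtx`) input needs companion one-column text files with gene
#' and cell (barcode) identifiers; the MTX convention of genes-in-rows is
#' assumed unless `cells_in_rows = TRUE`.
#'
#' @param path file to read.
#' @param format `"csv"`, `"tsv"` or `"mtx"`; default guessed from the
#'   extension.
#' @param cells_in_rows orientation of the stored matrix (default `TRUE`
#'   for dense, `FALSE` for MTX).
#' @param genes_file,barcodes_file identifier files for MTX input; default
#'   `genes.tsv` / `barcodes.tsv` next to the matrix.
#' @return validated numeric matrix, rows = cells, columns = genes.
#' @export
read_expression_matrix <- function(path, format = NULL, cells_in_rows = NULL,
                                   genes_file = NULL, barcodes_file = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(format)) {
    format <- switch(tolower(tools::file_ext(path)),
                     csv = "csv", tsv = "tsv", txt = "tsv", mtx = "mtx",
                     stop("cannot guess format of ", path, call. = FALSE))
  }
  if (format == "mtx") {
    if (is.null(cells_in_rows)) cells_in_rows <- FALSE
    m <- as.matrix(Matrix::readMM(path))
    dir <- dirname(path)
    genes_file <- genes_file %||% file.path(dir, "genes.tsv")
    barcodes_file <- barcodes_file %||% file.path(dir, "barcodes.tsv")
    genes <- readLines(genes_file)
    cells <- readLines(barcodes_file)
    if (!cells_in_rows) {
      if (nrow(m) != length(genes) || ncol(m) != length(cells)) {
        stop("MTX dimensions do not match genes/barcodes files", call. = FALSE)
      }
      dimnames(m) <- list(genes, cells)
      m <- t(m)
    } else {
      if (nrow(m) != length(cells) || ncol(m) != length(genes)) {
        stop("MTX dimensions do not match barcodes/genes files", call. = FALSE)
      }
      dimnames(m) <- list(cells, genes)
    }
  } else {
    if (is.null(cells_in_rows)) cells_in_rows <- TRUE
    sep <- if (format == "csv") "," else "\t"
    df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                            check.names = FALSE)
    m <- as.matrix(df)
    if (!is.numeric(m)) stop("matrix entries are not numeric", call. = FALSE)
    if (!cells_in_rows) m <- t(m)
  }
  validate_expression_matrix(m, require_names = TRUE)
  m
}

#' Write a matrix as TSV with identifiers
#'
#' Writes rows = cells, header row = gene/column names, first column
#' `cell_id`; the inverse of [read_expression_matrix()] for dense data.
#'
#' @param m matrix with row and column names.
#' @param path output path.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(cell_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes the shared backbone once — [preprocess_matrix()],
#' [select_features()], [train_stacked_vae()], [encode_cells()] — then each
#' requested downstream task on the single shared compressed matrix, and
#' writes one TSV per task plus a JSON run manifest (configuration, seed,
#' package version, timings) sufficient to reproduce the run.
#'
#' @param m expression matrix (cells x genes) or a path readable by
#'   [read_expression_matrix()].
#' @param tasks subset of `c("cluster", "visualize", "pseudotime")`;
#'   classification has its own entry point ([classify_cells()]) because it
#'   needs a second, labelled matrix.
#' @param out_dir output directory (created if missing).
#' @param n_keep,m_latent,n_replicates,k,k_nn,start_cell,embed_epochs task
#'   parameters; see the respective functions.
#' @param seed master seed; all stage seeds derive from it.
#' @param vae_args,fs_args extra arguments for the autoencoder trainers.
#' @return (invisibly) list with `latent`, per-task results, and
#'   `manifest`.
#' @export
run_pipeline <- function(m, tasks = c("cluster"), out_dir = ".",
                         n_keep = 5000L, m_latent = 15L,
                         n_replicates = 10L, k = NULL, k_nn = NULL,
                         start_cell = NULL, embed_epochs = 100L,
                         seed = 1L, vae_args = list(), fs_args = list()) {
  tasks <- match.arg(tasks, c("cluster", "visualize", "pseudotime"),
                     several.ok = TRUE)
  if ("pseudotime" %in% tasks && is.null(start_cell)) {
    stop("pseudotime requires a start_cell", call. = FALSE)
  }
  if (is.character(m) && length(m) == 1L) m <- read_expression_matrix(m)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  t0 <- Sys.time()
  timings <- list()

  x <- preprocess_matrix(m)
  fs <- do.call(select_features,
                c(list(x = x, n_keep = min(n_keep, ncol(x)),
                       seed = derive_seed(seed, 11L)), fs_args))
  vae <- do.call(train_stacked_vae,
                 c(list(x = fs$matrix, m = m_latent,
                        seed = derive_seed(seed, 12L)), vae_args))
  z <- encode_cells(vae, fs$matrix)
  timings$compress <- as.numeric(Sys.time() - t0, units = "secs")

  results <- list(latent = z)
  if ("cluster" %in% tasks) {
    t1 <- Sys.time()
    cl <- cluster_cells(fs$matrix, n_replicates = n_replicates, k = k,
                        k_nn = k_nn, seed = seed, vae_args = vae_args)
    utils::write.table(
      data.frame(cell_id = rownames(m), cluster = cl$labels),
      file.path(out_dir, "clusters.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    results$clustering <- cl
    timings$cluster <- as.numeric(Sys.time() - t1, units = "secs")
  }
  if ("visualize" %in% tasks) {
    t1 <- Sys.time()
    emb <- fit_embedding(z, epochs = embed_epochs,
                         seed = derive_seed(seed, 13L))
    utils::write.table(
      data.frame(cell_id = rownames(m), emb$coords),
      file.path(out_dir, "embedding.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    results$embedding <- emb
    timings$visualize <- as.numeric(Sys.time() - t1, units = "secs")
  }
  if ("pseudotime" %in% tasks) {
    t1 <- Sys.time()
    pt <- infer_pseudotime(z, start_cell)
    utils::write.table(
      data.frame(cell_id = names(pt$times), pseudotime = pt$times),
      file.path(out_dir, "pseudotime.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    results$pseudotime <- pt
    timings$pseudotime <- as.numeric(Sys.time() - t1, units = "secs")
  }

  manifest <- list(
    package = "schae",
    version = as.character(utils::packageVersion("schae")),
    seed = seed, tasks = tasks,
    config = list(n_keep = n_keep, m_latent = m_latent,
                  n_replicates = n_replicates, k = k, k_nn = k_nn,
                  start_cell = start_cell, embed_epochs = embed_epochs,
                  vae_args = vae_args, fs_args = fs_args),
    n_cells = nrow(m), n_genes = ncol(m),
    timings_sec = timings,
    r_version = R.version.string
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  results$manifest <- manifest
  invisible(results)
}

#' Adjusted Rand index between two partitions
#'
#' Thin wrapper over [mclust::adjustedRandIndex()] so that evaluation code
#' and logs use one entry point.
#'
#' @param a,b label vectors of equal length.
#' @return scalar ARI (1 = identical partitions, ~0 = random agreement).
#' @export
adjusted_rand_index <- function(a, b) {
  mclust::adjustedRandIndex(a, b)
}
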