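# Non-branching pseudotime: Pearson-distance graph over the compressed
# cells, minimum spanning tree, and time = tree-path distance from a
# user-designated starting cell. Every cell receives a finite time because
# the MST is connected by construction.

#' Infer a non-branching pseudotime ordering
#'
#' Builds the complete graph whose edge weights are Pearson distances
#' (`1 - r`) between latent vectors, extracts its minimum spanning tree
#' (Prim's algorithm; deterministic for a fixed input, and exact weight
#' ties between distinct cell pairs have measure zero for continuous
#' latent vectors), and reports each cell's pseudotime as the total edge
#' weight of its unique tree path from the designated starting cell.
#'
#' @param z compressed matrix (cells x latent dims), at least 2 cells.
#' @param start_cell row name (or index) of the starting cell; its time
#'   is 0.
#' @return object of class `pseudotime_result`: list with `times`
#'   (named, non-negative, finite), `start_cell`, and `tree_edges` (data
#'   frame `from`, `to`, `weight` with `n - 1` rows).
#' @export
infer_pseudotime <- function(z, start_cell) {
  stopifnot(is.matrix(z))
  n <- nrow(z)
  if (n < 2L) stop("need at least 2 cells", call. = FALSE)
  ids <- rownames(z) %||% as.character(seq_len(n))
  if (is.character(start_cell)) {
    start <- match(start_cell, ids)
    if (is.na(start)) stop("start cell '", start_cell, "' not found", call. = FALSE)
  } else {
    start <- as.integer(start_cell)
    if (start < 1L || start > n) stop("start cell index out of range", call. = FALSE)
  }

  d <- 1 - row_cor(z)
  d[d < 0] <- 0
  g <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  tree <- igraph::mst(g, algorithm = "prim")
  times <- as.numeric(igraph::distances(tree, v = start,
                                        weights = igraph::E(tree)$weight))
  names(times) <- ids

  el <- igraph::as_edgelist(tree, names = FALSE)
  edges <- data.frame(from = ids[el[, 1L]], to = ids[el[, 2L]],
                      weight = igraph::E(tree)$weight,
                      stringsAsFactors = FALSE)
  structure(list(times = times, start_cell = ids[start], tree_edges = edges),
            class = "pseudotime_result")
}

#' Variance in developmental stage explained by pseudotime
#'
#' Coefficient of determination of the simple linear regression of numeric
#' stage rank on inferred pseudotime, computed in closed form
#' (`R^2 = cor(time, rank)^2`). Quantifies how well a non-branching
#' trajectory recapitulates ordered developmental stages.
#'
#' @param times per-cell pseudotime values.
#' @param stages per-cell ordinal stage labels (ordered factor, or any
#'   vector whose sort order is the developmental order).
#' @return scalar in `[0, 1]`; constant times return 0 with a warning.
#' @export
fit_stage_r2 <- function(times, stages) {
  stopifnot(length(times) == length(stages))
  if (length(unique(stages)) < 2L) {
    stop("need at least 2 distinct stages", call. = FALSE)
  }
  if (stats::sd(times) == 0) {
    warning("constant pseudotime values; returning R^2 = 0")
    return(0)
  }
  rank_num <- if (is.ordered(stages)) {
    as.numeric(stages)
  } else {
    as.numeric(factor(stages, levels = sort(unique(stages))))
  }
  unname(stats::cor(times, rank_num)^2)
}
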