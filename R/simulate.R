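# Synthetic scRNA-seq generator: grouped negative-binomial counts with
# log-normal library sizes, optional extra dropout (zero inflation) tuned
# to a target sparsity, batch-shifted variants, and a linear-trajectory
# mode. Emulates the generative family of count simulators used for
# benchmarking single-cell methods without depending on one.

sim_base_means <- function(n_genes, mean_shape, mean_rate) {
  stats::rgamma(n_genes, shape = mean_shape, rate = mean_rate) + 0.1
}

apply_dropout <- function(counts, dropout_target) {
  if (is.null(dropout_target)) return(counts)
  stopifnot(dropout_target >= 0, dropout_target < 1)
  z0 <- mean(counts == 0)
  if (z0 > dropout_target + 0.02) {
    stop(sprintf(
      "infeasible dropout_target %.2f: baseline sparsity is already %.2f",
      dropout_target, z0), call. = FALSE)
  }
  if (z0 < dropout_target) {
    p_extra <- (dropout_target - z0) / (1 - z0)
    nz <- which(counts != 0)
    drop <- nz[stats::runif(length(nz)) < p_extra]
    counts[drop] <- 0
  }
  counts
}

#' Simulate a grouped or trajectory scRNA-seq count matrix
#'
#' Draws negative-binomial counts `NB(mu = lib_i * mean_{g(i), j},
#' size = 1/dispersion)` where each group has its own mean profile: a
#' disjoint block of `de_fraction * n_genes` genes per group is
#' up-regulated by `fold_change`, all other genes share one mean across
#' groups. Per-cell library factors are log-normal. If the realized zero
#' fraction falls short of `dropout_target`, additional entries are zeroed
#' at random (technical dropout) until the expected sparsity matches; a
#' baseline sparsity already above the target is an error. In trajectory
#' mode groups are replaced by a continuous gradient: each marker gene's
#' mean scales as `fold_change^(s * t)` with `s = +/-1` along the true
#' pseudotime `t` in `[0, 1]`.
#'
#' @param n_cells,n_genes matrix dimensions (defaults 600 x 2000, the small
#'   full-pipeline fixture).
#' @param n_groups number of cell groups (default 3; ignored in trajectory
#'   mode).
#' @param group_prop group proportions summing to 1 (default equal).
#' @param de_fraction fraction of genes differentially expressed per group
#'   (default 0.1).
#' @param fold_change up-regulation factor for DE genes (> 1, default 3).
#' @param dispersion negative-binomial dispersion (`size = 1/dispersion`,
#'   default 0.5).
#' @param dropout_target realized zero fraction to aim for (default 0.3,
#'   the low end of typical droplet sparsity); `NULL` disables the
#'   inflation step.
#' @param lib_sd sd of the log-normal library factor (default 0.2).
#' @param mean_shape,mean_rate gamma hyperparameters of the base gene
#'   means (defaults 2 and 0.5).
#' @param trajectory simulate a linear trajectory instead of groups.
#' @param traj_gene_fraction,traj_fold trajectory-mode analogues of
#'   `de_fraction` and `fold_change` (defaults 0.4 and 8): developmental
#'   series remodel a large share of the transcriptome with strong
#'   amplitude, so the trajectory defaults are deliberately stronger than
#'   the group-mode ones.
#' @param seed RNG seed; the same spec and seed reproduce the matrix
#'   exactly.
#' @return list with `counts` (cells x genes with `cell_*` / `gene_*`
#'   names), `labels` (integer groups; `NULL` in trajectory mode),
#'   `true_times` (trajectory mode only), `group_means` (groups x genes
#'   expected means), `de_genes` (list of per-group DE gene indices), and
#'   `lib_factors`.
#' @export
simulate_cells <- function(n_cells = 600L, n_genes = 2000L, n_groups = 3L,
                           group_prop = NULL, de_fraction = 0.1,
                           fold_change = 3, dispersion = 0.5,
                           dropout_target = 0.3, lib_sd = 0.2,
                           mean_shape = 2, mean_rate = 0.5,
                           trajectory = FALSE, traj_gene_fraction = 0.4,
                           traj_fold = 8, seed = 1L) {
  stopifnot(n_cells >= 2L, n_genes >= 2L, fold_change > 1, dispersion > 0)
  if (is.null(group_prop)) group_prop <- rep(1 / n_groups, n_groups)
  stopifnot(length(group_prop) == n_groups,
            abs(sum(group_prop) - 1) < 1e-8, all(group_prop > 0))
  set.seed(seed)

  base <- sim_base_means(n_genes, mean_shape, mean_rate)
  n_de <- round(de_fraction * n_genes)
  lib <- exp(stats::rnorm(n_cells, 0, lib_sd))
  size <- 1 / dispersion

  if (trajectory) {
    tt <- stats::runif(n_cells)
    n_traj <- round(traj_gene_fraction * n_genes)
    de_idx <- if (n_traj > 0) sample.int(n_genes, min(n_traj, n_genes)) else integer(0)
    slope <- numeric(n_genes)
    slope[de_idx] <- sample(c(-1, 1), length(de_idx), replace = TRUE) *
      log(traj_fold)
    mu <- outer(tt, slope, function(t, s) exp(s * t)) *
      rep(base, each = n_cells) * lib
    counts <- matrix(stats::rnbinom(n_cells * n_genes, mu = mu, size = size),
                     n_cells, n_genes)
    counts <- apply_dropout(counts, dropout_target)
    labels <- NULL; group_means <- NULL
    de_genes <- list(sort(de_idx)); true_times <- tt
  } else {
    if (n_groups * n_de > n_genes) {
      stop("de_fraction too large for disjoint per-group DE blocks", call. = FALSE)
    }
    de_genes <- if (n_de > 0) {
      split(sample.int(n_genes, n_groups * n_de),
            rep(seq_len(n_groups), each = n_de))
    } else {
      replicate(n_groups, integer(0), simplify = FALSE)
    }
    group_means <- matrix(base, n_groups, n_genes, byrow = TRUE)
    for (gidx in seq_len(n_groups)) {
      group_means[gidx, de_genes[[gidx]]] <-
        group_means[gidx, de_genes[[gidx]]] * fold_change
    }
    labels <- sample.int(n_groups, n_cells, replace = TRUE, prob = group_prop)
    mu <- group_means[labels, , drop = FALSE] * lib
    counts <- matrix(stats::rnbinom(n_cells * n_genes, mu = mu, size = size),
                     n_cells, n_genes)
    counts <- apply_dropout(counts, dropout_target)
    true_times <- NULL
  }

  dimnames(counts) <- list(paste0("cell_", seq_len(n_cells)),
                           paste0("gene_", seq_len(n_genes)))
  list(counts = counts, labels = labels, true_times = true_times,
       group_means = group_means, de_genes = de_genes,
       lib_factors = lib, seed = seed)
}

#' Simulate batch-shifted replicates of one grouped population
#'
#' Draws `n_batches` count matrices that share the same group structure and
#' expected group means, then applies a batch-specific multiplicative shift
#' of `batch_fold` to a random `batch_gene_fraction` of genes in every
#' batch after the first (the first batch is the reference). Intended for
#' testing cross-batch classification: labels transfer across batches, but
#' raw expression does not.
#'
#' @param n_batches number of batches (>= 2).
#' @param batch_gene_fraction fraction of genes shifted per batch
#'   (default 0.1).
#' @param batch_fold multiplicative shift on the affected genes
#'   (default 2; 1 disables the batch effect).
#' @param seed master seed; per-batch seeds are derived from it.
#' @inheritParams simulate_cells
#' @param ... further arguments for [simulate_cells()].
#' @return list of length `n_batches`; each element is a
#'   [simulate_cells()] result with an extra `batch_genes` field (indices
#'   of shifted genes; empty for the reference batch).
#' @export
simulate_cell_batches <- function(n_batches = 2L, batch_gene_fraction = 0.1,
                                  batch_fold = 2, n_cells = 600L,
                                  n_genes = 2000L, n_groups = 3L,
                                  group_prop = NULL, dispersion = 0.5,
                                  dropout_target = 0.3, lib_sd = 0.2,
                                  seed = 1L, ...) {
  stopifnot(n_batches >= 2L)
  if (is.null(group_prop)) group_prop <- rep(1 / n_groups, n_groups)
  # shared group-mean structure for all batches
  ref <- simulate_cells(n_cells = n_cells, n_genes = n_genes,
                        n_groups = n_groups, group_prop = group_prop,
                        dispersion = dispersion,
                        dropout_target = dropout_target, lib_sd = lib_sd,
                        seed = seed, ...)
  gm0 <- ref$group_means
  size <- 1 / dispersion
  out <- vector("list", n_batches)
  for (b in seq_len(n_batches)) {
    sim <- ref
    if (b > 1L) {
      set.seed(derive_seed(seed, 100L + b))
      labels <- sample.int(n_groups, n_cells, replace = TRUE,
                           prob = group_prop)
      shift_genes <- sort(sample.int(
        n_genes, round(batch_gene_fraction * n_genes)))
      gm <- gm0
      if (batch_fold != 1) {
        gm[, shift_genes] <- gm[, shift_genes] * batch_fold
      }
      lib <- exp(stats::rnorm(n_cells, 0, lib_sd))
      mu <- gm[labels, , drop = FALSE] * lib
      counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = size),
                       n_cells, n_genes)
      counts <- apply_dropout(counts, dropout_target)
      dimnames(counts) <- list(paste0("b", b, "_cell_", seq_len(n_cells)),
                               paste0("gene_", seq_len(n_genes)))
      sim$counts <- counts
      sim$labels <- labels
      sim$lib_factors <- lib
      sim$batch_genes <- if (batch_fold != 1) shift_genes else integer(0)
    } else {
      rownames(sim$counts) <- paste0("b1_", rownames(sim$counts))
      sim$batch_genes <- integer(0)
    }
    out[[b]] <- sim
  }
  out
}
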