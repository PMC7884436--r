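# schae — hierarchical autoencoder analysis of single-cell transcriptomes

Single-cell RNA-seq matrices are large, sparse, and noisy: tens of
thousands of genes per cell, most entries zero, and technical variation
that easily swamps biology. `schae` addresses this with a two-stage
hierarchical autoencoder, for anyone who needs cell types, a 2-D map,
transferred labels, or a developmental ordering out of an expression
matrix:

1. a **non-negative kernel autoencoder** (one linear layer, encoder weights
   clamped ≥ 0) whose encoder-weight variances score genes; the top 5000
   genes are kept;
2. a **stacked Bayesian autoencoder** — a variational autoencoder
   `e = f_E(x)`, `μ = f_μ(e)`, `σ = f_σ(e)`, `z = μ + σ·ε`, `x̄ = f_D(z)`
   whose reconstruction loss averages several realizations of `z` — trained
   in two stages (reconstruction-only warm-up, then + `KL(N(μ,σ²) ‖ N(0,I))`)
   with AdamW and SELU activations, compressing each cell to `m = 15`
   dimensions.

On the compressed space the package performs:

* **cell segregation** — k-nearest-neighbour spectral clustering on a
  Pearson-similarity graph (`L = I − D^{−1/2} A D^{−1/2}`), the cluster
  count estimated from two sum-of-squares indices
  (`SS_between/SS_total` and the within-SS spike), replicate runs merged by
  weighted meta-clustering (`w_ij = s_ij(1 − s_ij)`), with a k-nn voting
  shortcut for very large data;
* **visualization** — a small network trained to minimize `KL(P ‖ Q)`
  between high- and low-dimensional neighbourhood distributions built from
  row-standardized log distances;
* **classification** — transductive: concatenate train and test on common
  genes, compress jointly, label test cells by k-nn Pearson similarity;
* **pseudotime** — minimum spanning tree of the Pearson-distance graph;
  time = tree distance from a designated start cell.

All three networks are written in plain R matrix algebra with analytic
gradients (finite-difference-verified in the tests) and a hand-written
AdamW optimizer. A negative-binomial simulator with dropout, batch shifts,
and linear trajectories makes everything testable offline.

## Worked example

Simulate five cell types with 30% dropout, then cluster:

```r
library(schae)

sim <- simulate_cells(n_cells = 1000, n_genes = 2000, n_groups = 5,
                      dropout_target = 0.3, seed = 5)
x   <- preprocess_matrix(sim$counts)          # log rule + per-cell min-max
cl  <- cluster_cells(x, n_replicates = 3, seed = 42)
#> predicted number of clusters: 5
adjusted_rand_index(cl$labels, sim$labels)
#> [1] 1
```

The estimator read the correct number of populations (5) off the latent
space, and the consensus partition matches the generating labels exactly
(ARI 1; ARI ≈ 0 would mean chance agreement). Pseudotime on a simulated
developmental series, compressing first, then ordering from the earliest
cell:

```r
simt <- simulate_cells(n_cells = 300, n_genes = 1000, trajectory = TRUE, seed = 7)
xt   <- preprocess_matrix(simt$counts)
vt   <- train_stacked_vae(xt, seed = 8)
zt   <- encode_cells(vt, xt)
pt   <- infer_pseudotime(zt, rownames(zt)[which.min(simt$true_times)])
cor(pt$times, simt$true_times, method = "spearman")
#> [1] 0.9306699
```

Inferred times track the planted ordering at Spearman ρ ≈ 0.93. A thin
command-line wrapper over the same functions ships in `inst/cli/schae.R`
(subcommands `simulate`, `compress`, `cluster`, `visualize`, `classify`,
`pseudotime`).

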