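# spotglue

Integration of multiple spatial transcriptomics slices — across platforms,
resolutions and conditions — into a shared low-dimensional embedding, using
community-enhanced graph contrastive learning.

## The problem

A spatial transcriptomics experiment yields one tissue section: a spots ×
genes count matrix with a 2-D coordinate per spot. Joint analysis of
several sections (serial slices, different platforms such as Visium vs
Stereo-seq, healthy vs diseased tissue) needs all spots in one embedding
in which spatial domains (e.g. cortical layers) stay separable while
platform- and sample-specific batch effects disappear. spotglue is for
analysts who have two or more such slices and want integrated embeddings,
spatial-domain calls, denoised expression, and the standard
integration-quality metrics.

## The method

Each slice becomes a spatial neighbor graph: Delaunay edges of the spot
coordinates pruned at twice the mean k-nearest-neighbor radius (an
alpha-complex construction robust to non-uniform spot densities). A single
two-layer graph-convolutional encoder

  Z = Â · PReLU(Â X W₁ + b₁) · W₂ + b₂,  Â = D̃⁻¹ᐟ²(A+I)D̃⁻¹ᐟ²

is trained across all slices in two stages. Stage 1 contrasts two
uniformly perturbed graph views of each slice with a symmetrized InfoNCE
loss over cosine similarities. At the stage boundary, Leiden communities
are detected per slice and scored by their modularity contribution

  S_c = E_c/|E| − (Σ_{v∈c} d_v)² / (4|E|²),   Σ_c S_c = Q.

Stage 2 perturbs views by communal attribute voting (genes carrying more
community-specific signal are masked more often) and communal edge
dropping (cross-community edges are usually removed), and adds a scheduled
community bonus γ_k(H_i + H_j)S to every similarity term. Two further
objectives shape the embedding: a spatial similarity constraint
Σᵢⱼ D^s_ij (1 − D^Z_ij)/n², and a cross-slice triplet loss
max(‖Z_a − Z_p‖² − ‖Z_a − Z_n‖² + θ, 0) over mutual-nearest-neighbor
pairs, re-detected every 100 epochs, which performs the batch-effect
removal. The total loss

  L = Σ_t L_t + α Σ_t L_within^t + β Σ_{t₁<t₂} L_across^{t₁t₂}

is minimized with Adam (learning rate 0.001). A symmetric two-layer
decoder fitted to the frozen embeddings provides expression denoising.

Everything model-specific (encoder, losses, gradients, optimizer) is
implemented in the package, with the heavy loss kernels in
RcppArmadillo; graph, clustering and neighbor machinery use igraph,
deldir, RANN, mclust and cluster.

## Worked example

Simulate two layered-tissue slices (5 domains, 300 genes, ~1,500 spots
each at a 2× resolution difference, strong gene-wise batch shift),
integrate, and score:

```r
library(spotglue)

sim <- simulate_slices(sim_config(seed = 1))
sl  <- lapply(sim$slices, preprocess)
sh  <- select_shared_hvgs(sl, n_top = 3000, raw_slices = sim$slices)

fit <- integrate_slices(sh$slices, epochs = 500, stage1_epochs = 100,
                        mnn_refresh = 100, seed = 1)
je  <- joint_embedding(fit)
labels <- unlist(lapply(sim$labels, as.character))

# before integration the slices are completely separated in expression PCA
Xall <- do.call(rbind, lapply(sh$slices, function(s) s$X))
batch_entropy(prcomp(Xall, rank. = 20)$x, je$batch)
#> [1] 0

batch_entropy(je$Z, je$batch)
#> [1] 0.8750447
cl <- cluster_embeddings(je$Z, "leiden", n_clusters = 5, seed = 1)
adjusted_rand_index(cl, labels)
#> [1] 0.9490412
```

A normalized batch entropy of 0 means every spot's embedding neighborhood
comes from its own slice (no mixing); after integration it rises to 0.88
(1.0 would be perfectly proportional mixing). The adjusted Rand index of
0.95 against the simulated ground-truth domains means Leiden clustering of
the integrated embedding essentially recovers the five tissue layers.
Denoising through the fitted decoder raises the median marker-gene
correlation with the true noiseless means from 0.35 (raw log-normalized
counts) to 0.70:

```r
dec <- fit_decoder(fit$embeddings, lapply(sh$slices, function(s) s$X),
                   epochs = 500, seed = 1)
den <- denoise(fit$embeddings[[1]], dec)
```

`tidy(fit)` returns the per-epoch loss components, `glance(fit)` a one-row
summary, and `plot_loss_history(fit)` / `plot_embedding(fit)` the usual
diagnostics. Slices are read and written with `load_slice()` /
`write_slice_h5ad()` (h5ad, MatrixMarket directory, or CSV; files
interoperate with the Python anndata ecosystem). A command-line wrapper
with `simulate`, `integrate`, `metrics` and `denoise` subcommands lives at
`inst/cli/spotglue.R`.

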