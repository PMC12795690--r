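# ptppi

Protein–protein interaction (PPI) prediction from protein **surface point
clouds**, **spherical convex hull (SCHull) graphs** and a **Point
Transformer** network fused with protein sequence embeddings.

## Who this is for

Structural bioinformaticians who want a self-contained, inspectable
implementation of geometric deep learning on molecular surfaces: every
stage — surface sampling, featurisation, graph construction, attention,
training, evaluation — is exposed as an R function with deterministic
behaviour, and the whole framework runs end to end on synthetic dimers
with no external downloads.

## The method

For each chain of a ligand–receptor pair:

1. **Oriented surface.** Atoms define a smooth-min distance field
   `f(x) = -s log Σ_k exp(-(‖x - a_k‖ - r_k)/s)`; surface points are
   converged onto the level set `f = o` and carry outward unit normals
   (the normalised analytic gradient).
2. **32-dim point features.** 22 chemical channels (inverse-distance mix
   of one-hot element vectors over a 22-symbol vocabulary) plus 10
   curvature channels: `det(S_σ)` and `trace(S_σ)` of a local 2×2 shape
   operator at scales σ ∈ {1, 2, 3, 5, 10} Å. On a sphere of radius R,
   `det(S) = 1/R²` and `trace(S) = 2/R`.
3. **SCHull graph.** Project points onto a unit sphere about their
   centroid, take the 3-D convex hull of the projections, and connect two
   points iff the hull joins their projections. The graph is always
   connected, has at most `3N − 6` undirected edges, needs no distance or
   neighbour-count hyperparameter, and is invariant to rigid motion and
   scale. Radius-cutoff and k-NN builders are included as baselines.
4. **Point Transformer.** Nodes are encoded by
   `h⁰ = dropout(ReLU(LayerNorm(W_in x)))` plus a learned positional term
   `hΘ(p_i − p_j)` averaged over the neighbourhood, then updated by
   vector-attention layers
   `x_i' = Σ_{j∈N(i)} α_ij ⊙ (W₃ x_j + δ_ij)`,
   `α_ij = softmax_j(γΘ(W₁ x_i − W₂ x_j + δ_ij))`.
   Node embeddings are mean-pooled per chain, concatenated with projected
   1024-wide pooled sequence embeddings, and a two-layer head emits the
   interaction probability. Forward pass, analytic backpropagation and
   Adam are implemented in base R; the convex hull and curvature kernels
   are in C++ (Rcpp).

Ablation switches cover: no sequence branch, no positional encoder,
attention stack replaced by an MLP, and 1–5 transformer layers.

## Worked example

```r
library(ptppi)

# a synthetic dimer dataset: 120 pairs, balanced labels, geometric +
# sequence interaction signal, fully deterministic
spec <- synthetic_spec(n_pairs = 120, complementarity_strength = 1,
                       sequence_signal_strength = 1, rng_seed = 42)
ds <- generate_synthetic_dataset(spec)
ds[[2]]
#> <pair_sample> pair00002 label=1 | L: 92 atoms/35 pts, R: 278 atoms/66 pts

folds <- make_splits(ds, k = 4, seed = 9)
model <- ptppi_train(ds[folds != 1], ds[folds == 1],
                     model_config(hidden_dim = 32, num_pt_layers = 2),
                     train_config(learning_rate = 1e-3, max_epochs = 25,
                                  patience = 25, rng_seed = 1))
model
#> <ptppi_model> H=32, 2 PT layer(s), pos.enc=TRUE, sequence=TRUE |
#>   trained 25 epochs (best 22, val loss 0.1889)

evaluate_pairs(model, ds[folds == 1])
#> <metrics_record> n=30 acc=0.967 prec=0.938 rec=1.000 f1=0.968
#>   auroc=0.996 auprc=0.996
```

The held-out fold of 30 pairs is classified at 96.7% accuracy with AUROC
0.996: the network recovers both the boss/pocket surface complementarity
and the sequence-motif signal planted by the generator. With both signal
strengths set to 0 the same protocol stays at chance (AUROC ≈ 0.5).

Single structures go through the same machinery:

```r
cloud <- read_structure("complex.pdb", "pdb")
chains <- split_chains(cloud)
surf  <- featurize(chains[[1]], sampler_config(rng_seed = 1))
graph <- build_schull(surf$points, x = surf$features)
edge_features(graph)   # distances (Å) and hull dihedrals (rad)
```

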