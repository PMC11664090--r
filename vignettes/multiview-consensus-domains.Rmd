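---
title: "Multi-view consensus clustering of spatial transcriptomics: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-view consensus clustering of spatial transcriptomics: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(spatialmvc)
```

This vignette is the package's own account of the method it implements:
the model and its assumptions, the parameters that matter, what the
synthetic generator does and does not emulate, and the design choices
made where the design was genuinely open.  It states no empirical result
that the test suite does not itself compute.

## The model

### Views

A *view* is one binary, symmetric, zero-diagonal spot-adjacency matrix
$A^{(i)}$.  Four constructions are provided:

* **radius**: $A_{ij} = 1$ iff $0 < d(i,j) < r$ (strict inequality at the
  boundary).  The default $r$ is $1.5\times$ the median nearest-neighbor
  distance, which on a Visium-style hexagonal lattice with unit spacing
  connects each interior spot to exactly its six lattice neighbors.
* **knn**: each spot selects its $k$ nearest neighbors (default
  $k = 6$, the hexagonal neighbor count); the directed graph is
  OR-symmetrized, so row sums can exceed $k$.  Distance ties at the
  $k$-boundary break by lower spot index, making results platform- and
  backend-independent.
* **spearman** / **cosine**: the same top-$k$ selection applied to rank
  correlation / cosine similarity between spots' expression profiles.

The radius and knn builders accept a `backend` label (`balltree`,
`kdtree`).  Both searches here are exact, so the two backends return
identical graphs; the label is kept as construction metadata because the
four spatially built views are conventionally named by the search
structure used to build them.  We implement one exact search and document
the coincidence rather than simulating implementation-specific tie
behavior we cannot observe.

Spearman correlation is computed between each *pair of spots over their
feature vectors* (average ranks on ties).  A formulation that ranges the
sum over "the number of spots" appears in some descriptions; that is a
transcription slip — the classical rank correlation over feature vectors
is the only reading under which the similarity is well defined.

### Per-view variational graph auto-encoder

With $S = D^{-1/2}(A+I)D^{-1/2}$, the encoder is

$$Z_f = \mathrm{FC}(X), \quad
  Z_g = \mathrm{ReLU}(S\,Z_f W_1), \quad
  \mu = S\,Z_g W_\mu, \quad
  \log\sigma^2 = S\,Z_g W_\sigma ,$$

i.e. the mean and log-variance convolutions share the first graph layer
($W_1$) and differ only in their second-layer weights.  Sampling uses the
standard reparameterization $z = \mu + e^{\frac{1}{2}\log\sigma^2}\odot
\varepsilon$.  A formulation multiplying $\log\sigma^2$ by $\varepsilon$
directly is sometimes written; it is not a valid sampler (it breaks for
$\log\sigma^2 \le 0$) and contradicts the variational-autoencoder
literature it cites, so a strict-literal mode is deliberately not
provided.

Decoders: $\tilde A = \mathrm{sigmoid}(ZZ^\top)$ and a mirror linear
stack for $\tilde X$.  Loss terms, all minimized:

* $L_A$: mean squared error between $A$ (self-loops excluded) and
  $\tilde A$, with edges re-weighted by the non-edge/edge ratio.  Spatial
  graphs are ~1% dense, so without class balancing the all-zero
  reconstruction is a near-optimum.
* $L_X = \mathrm{mean}\,(X - \tilde X)^2$.
* $L_{KL}$: the negated evidence lower bound — balanced binary
  cross-entropy of $\tilde A$ plus the Gaussian divergence
  $-\tfrac12\,\mathrm{mean}(1 + \log\sigma^2 - \mu^2 - \sigma^2) \ge 0$.

The total is $\lambda_1 L_A + \lambda_2 L_X + \lambda_3 L_{KL} +
\lambda_4 L_{DEC}$.  Keeping both $L_A$ and the cross-entropy term inside
$L_{KL}$ is redundant in spirit but is exactly what the overall loss
prescribes; the weights let either be switched off.

### Self-supervised clustering head

After `pretrain_epochs` without self-supervision, cluster centers are
initialized from a Gaussian-mixture clustering of the noise-free
embedding $\mu$.  The soft assignment is the degree-1 Student-t kernel

$$q_{ij} = \frac{(1+\lVert z_i-\mu_j\rVert^2)^{-1}}
                {\sum_{j'}(1+\lVert z_i-\mu_{j'}\rVert^2)^{-1}},$$

the target $p_{ij} \propto q_{ij}^2 / \sum_i q_{ij}$ (renormalized per
row) sharpens high-confidence assignments, and $L_{DEC} = \sum_{ij}
p_{ij}\log(p_{ij}/q_{ij})$.  The target refreshes every `dec_interval`
epochs.  During training $q$ is computed from the sampled $z$; at
evaluation the embedding is $\mu$ — whether the original procedure used
the sample or the mean is unstated, and the sampled choice keeps the head
consistent with the rest of the stochastic training pass.

All gradients — including the closed-form DEC gradients
$\partial L/\partial z_i = 2\sum_j k_{ij}(p_{ij}-q_{ij})(z_i-\mu_j)$ —
are hand-derived and checked against central finite differences in
`test-vgae.R`.

### Consensus

Each view's $\mu$ is clustered by a full-covariance Gaussian mixture
(EM, k-means initializations, 10 restarts, ridge-regularized
covariances).  The consensus matrix $C_{ij}$ is the fraction of views in
which $i$ and $j$ co-cluster; the final partition cuts the
average-linkage dendrogram of $1-C$ at $K$.  Because $C$ only counts
co-membership, it is invariant to each view's arbitrary cluster
numbering — no label alignment across views is needed.  Average linkage
is the standard choice in consensus clustering; single linkage chains
through noisy co-cluster entries and complete linkage over-fragments.

## Parameters that matter

| parameter | default | why |
|---|---|---|
| `min_cells` | 50 spots | standard gene filter for spot-level data |
| `n_hvg` | 3000 | standard highly-variable-gene budget |
| `target_sum` | median library size | scale-free normalization target |
| `r` (radius views) | 1.5 × median NN distance | reproduces the 6-neighbor hexagonal structure |
| `k` (knn/expression views) | 6 | hexagonal neighbor count |
| `fc_dims` | 1000, 500, 30 | mid-grid stack for 3000-gene input; scale down for smaller panels |
| `gcn_hidden`, `latent_dim` | 64, 8 | graph-convolution widths |
| `λ₁…λ₄` | 1, 1, 1, 0.1 | DEC down-weighted so it refines rather than dominates |
| `pretrain/train epochs` | 200 + 200 | unstated upstream; declared defaults |
| `dec_interval` | 20 epochs | target-refresh cadence |
| `α₁, α₂` | 0.3, 1.0 | image features auxiliary to expression |
| EM `restarts` | 10 | best-likelihood restart wins |

Epoch counts, λ weights and α weights have no authoritative values; the
defaults above are declared once here and used everywhere, including the
acceptance tests.

## The synthetic generator

`simulate_dataset()` emulates: an offset-row hexagonal lattice with unit
nearest-neighbor spacing (six neighbors per interior spot, as on a Visium
array); $K$ contiguous horizontal bands as domains (mirroring laminar
tissue such as cortical layers, and making within-domain connectivity
true by construction); negative-binomial counts with
`markers_per_domain` disjoint marker genes per domain whose mean is
`baseline_mean · 2^lfc` inside the domain; independent Bernoulli dropout;
optional flat-color pseudo-histology tiles with pixel noise.

Defaults (600 spots, 150 genes, $K=4$, 10 markers/domain, lfc 2.5,
baseline mean 2, dropout 0.3, NB size 2) are the benchmark world used by
the acceptance suite.  They were chosen once as a realistic-but-solvable
regime: the generator's own sanity property (k-means on PCA reaches
ARI ≥ 0.5) guarantees the benchmark is not vacuously hard.

What the generator does **not** emulate: spatially smooth within-domain
expression gradients, cell-type mixtures within spots, irregular domain
shapes, batch effects, real histology texture, or platform-specific
artifacts.  A green recovery test therefore establishes that the pipeline
can exploit spatial structure and marker signal under heavy sparsity —
not that it matches published performance on real tissue.

## Numerical choices

* All networks train full-batch with Adam (lr $10^{-3}$, weight decay
  $10^{-4}$ on weight matrices); everything is seeded and deterministic.
* Binary cross-entropy clamps probabilities by $10^{-12}$; `dec_loss`
  defines $0\log 0 = 0$ and clamps $q$ where $p>0$.
* EM covariances carry a $10^{-6}$ ridge, escalated tenfold on Cholesky
  failure; duplicated-point clouds therefore cluster without crashing.
* k-nearest-neighbor and top-$k$ similarity selections break ties by
  lower spot index; hierarchical clustering uses `stats::hclust`, whose
  tie behavior is deterministic for a fixed input.
* The aligner autoencoder standardizes its input per feature, and the
  aligned features are z-scored before the $\alpha$-weighted blend —
  without scale matching between CNN features and log-expression the
  blend weights would be meaningless.
* The logged total loss is only comparable within a fixed objective
  segment: the clustering term switches on at the phase boundary and its
  target sharpens at every refresh, so the total can step upward across
  those boundaries while every fixed-objective segment descends (and
  clustering improves).  The training-sanity tests assert descent per
  segment for exactly this reason.
* The normalized adjacency $D^{-1/2}(A+I)D^{-1/2}$ has eigenvalues in
  $(-1, 1]$; note its *row sums* are not bounded by 1 (a star graph's
  center exceeds it), so tests assert the spectral bound, not a row-sum
  bound.

## Design decisions made here

* **Backends as metadata** (see above): one exact neighbor search serves
  both tree labels.
* **Preprocessing order** filter → normalize → log1p → HVG: the upstream
  description is ambiguous ("log-transformed … and normalized"); the
  conventional toolkit order is adopted.
* **Augmentation operates on fully preprocessed expression**; the
  alternative (augment raw counts, then preprocess) would feed negative
  z-scored image features into a log transform.
* **The aligner's aligned layer is the target-dimension layer** of an
  expansion autoencoder (d0 → … → n_hvg → … → d0): the aligned features
  must match the expression dimension.
* **`n_clusters` is user-supplied** (ground-truth K), matching the
  evaluation practice of the field; no automatic model selection.
* **One clustering per view** feeds the consensus; nothing in the
  procedure requires repeated clusterings per view, and determinism is
  easier to reason about with one.
* **NMI uses arithmetic-mean normalization**, the common default; the
  exact variant used upstream is in supplementary material we do not
  reproduce.
* **JSON configs** instead of TOML/YAML: the pinned dependency set has a
  JSON parser; it does not have a TOML one.

## Scope and limitations

Downstream visualization (UMAP/PAGA), batch integration, spatially
variable gene detection, alternative graph-convolution layers (attention
variants), mini-batch training and approximate neighbor search are out of
scope; `conv_type` is an extension point restricted to the symmetric
normalized convolution.  The dense $n \times n$ adjacency algebra targets
desk scale (≤ a few thousand spots); real Visium sections (~4–5k spots)
fit, but whole-slide Stereo-seq data would need sparse rewrites.  The
acceptance suite's stability criterion compares the dispersion of
consensus ARI against per-view ARI over 10 seeds of the benchmark world;
it is a statistical statement about this generator, not a guarantee for
arbitrary data.
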