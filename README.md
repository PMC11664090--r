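# spatialmvc

Multi-view variational graph auto-encoders with consensus clustering for
spatial-domain identification in spot-level spatial transcriptomics.

## The problem

Spot-level spatial transcriptomics platforms (10x Visium, Stereo-seq, the
original ST arrays) measure a pooled transcriptome at each capture spot
together with the spot's position on the tissue section.  A central
analysis task is **spatial-domain identification**: partitioning the spots
into contiguous tissue regions — cortical layers, tumor vs. stroma — that
are coherent in both expression and space.  Single-graph methods commit to
one definition of "neighborhood"; this package instead trains one model
per *view* and merges the resulting partitions.

## The method

1. **Preprocessing.**  Genes seen in fewer than `min_cells` spots (default
   50) are removed; counts are library-size normalized and
   `log(1+x)`-transformed; the top `n_hvg` (default 3000) genes by
   mean-binned normalized dispersion are kept.
2. **Optional histology augmentation.**  Per-spot H&E tiles are mapped to
   feature vectors by a pluggable extractor (a deterministic built-in
   extractor replaces a pre-trained CNN in tests), aligned to the
   expression dimension by a small fully connected autoencoder
   (`MS`), and blended with expression: `X = α₁·MS + α₂·GE`.
3. **Views.**  Binary symmetric spot-adjacency matrices `A⁽ⁱ⁾`: fixed
   radius and k-nearest-neighbor graphs on coordinates, Spearman and
   cosine graphs on expression.  Each is normalized as
   `D^{-1/2}(A+I)D^{-1/2}`.
4. **Per-view VGAE.**  A linear stack produces `Z_f`; graph convolutions
   produce a Gaussian posterior `(μ, log σ²)` per spot; `z = μ +
   exp(½ log σ²)·ε`.  An inner-product decoder reconstructs the adjacency
   (`sigmoid(ZZᵀ)`) and a mirror stack reconstructs the features.  The
   loss is `λ₁L_A + λ₂L_X + λ₃L_KL + λ₄L_DEC`, where `L_DEC` is a deep
   embedded clustering head: a Student-t soft assignment `q` against
   learned centers, sharpened into a target `p` and pulled together by
   `KL(P‖Q)`.  Training is two-phase (pretrain without the DEC head, then
   joint).
5. **Consensus.**  Each view's embedding is clustered by a full-covariance
   Gaussian mixture (EM, 10 restarts).  The consensus matrix
   `C_ij = (1/N) Σ_n 1[y_i⁽ⁿ⁾ = y_j⁽ⁿ⁾]` is cut by average-linkage
   hierarchical clustering on `1 − C` into the final domains.

All numerics — the VGAE, the DEC head, the aligner autoencoder, the EM
mixture — are implemented in dense R matrix algebra with hand-derived
gradients (verified against numerical differentiation in the test suite).

## Worked example

```r
library(spatialmvc)

# a Visium-like lattice: 600 spots, 150 genes, 4 layered domains,
# log2 fold change 2.5 on 10 markers/domain, 30% dropout
ds <- simulate_dataset(sim_config(seed = 0))

cfg <- pipeline_config(
  preprocess = preprocess_config(min_cells = 50, n_hvg = 3000),
  model = model_config(fc_dims = c(128, 64), gcn_hidden = 64,
                       latent_dim = 8),
  n_clusters = 4, seed = 0)

out <- run_pipeline(ds, cfg)
print(out$metrics)
#> ARI 0.991 | NMI 0.987 | HS 0.987 | Purity 0.997 (n = 600)

sapply(out$result$view_labels,
       function(y) adjusted_rand_index(ds$truth_labels, y))
#> radius_ball    knn_ball    knn_kdtr
#>   0.8981119   0.5154239   0.9823119
```

The per-view ARIs show why the consensus step exists: one view's mixture
clustering landed in a poor solution (0.52), but the merged partition
(0.991) is better than every individual view.

## Command line

```sh
Rscript -e 'spatialmvc::mvc_cli()' simulate --out sim --k 4 --spots 600
Rscript -e 'spatialmvc::mvc_cli()' run --data sim --k-clusters 4 --seed 0 \
    --views radius_ball,knn_ball,knn_kd
Rscript -e 'spatialmvc::mvc_cli()' run --data sim --k-clusters 4 --no-dec \
    --no-consensus          # ablation switches
Rscript -e 'spatialmvc::mvc_cli()' sweep --data sim --k-clusters 4 \
    --subsets subsets.json --out sweep_out
```

`--config cfg.json` supplies any `pipeline_config()` field; flags
override the file.

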