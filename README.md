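# nestedtmap

Clustering and visualization of very large small-molecule libraries in R.

Modern make-on-demand screening libraries hold 10⁹–10¹⁰ compounds —
far beyond what pairwise-similarity clustering or a single 2D embedding
can handle. `nestedtmap` implements a pipeline designed for that regime
and fully usable at desk scale:

1. **MQN fingerprints.** Every molecule is represented by its 42
   molecular quantum numbers **x** ∈ ℕ₀⁴² — integer counts of atom and
   bond types, polar groups and topological features (computed with
   RDKit through a bundled batch interface).
2. **Product quantization (PQ).** Each vector is split into *m* = 6
   contiguous subvectors of dimension 7. A codebook of *L* = 256
   codewords per subspace is learned by k-means (greedy k-means++
   initialization, L2, 20 Lloyd iterations) on a training subsample, and
   every molecule is encoded as the 6-tuple of nearest-codeword indices
   (c₁,…,c₆), cᵢ ∈ {0,…,255}: a 6-byte code, a 7-fold compression.
3. **Symmetric distance (SD).** With precomputed L×L tables Tⱼ of
   squared codeword distances, distances never touch the original
   vectors: SD(a, b) = √(Σⱼ Tⱼ[aⱼ, bⱼ]). SD equals the true Euclidean
   distance exactly whenever both vectors are codeword-exact.
4. **PQk-Means.** A Lloyd alternation entirely in code space: SD
   assignment, then an exact per-subspace centroid update (histogram of
   member indices × Tⱼ, argmin over codewords), so the objective is
   provably non-increasing. Empty clusters are compacted away after the
   final streaming assignment; each surviving cluster is summarized by
   the member with minimal SD to its centroid.
5. **Nested tree-maps.** A primary map organizes the cluster
   representatives: k-nearest-neighbour graph on MQN (Euclidean) →
   minimum spanning tree → deterministic 2D layout. Every node links to
   a secondary map of that cluster's members organized by
   ECFP4/Tanimoto similarity, so the whole library is reachable in two
   clicks while no single map exceeds roughly √N nodes.

The package also ships cluster-quality diagnostics (SD-vs-Euclidean
agreement, within/between-cluster distance sampling, blocked distance
heatmaps, per-cluster descriptor dispersion), a sharded streaming
pipeline with a run manifest, synthetic fixture generators, and a thin
CLI (`inst/cli/nestedtmap.R`).

## Worked example

```r
library(nestedtmap)

lib    <- generate_smiles_library(400, seed = 7)   # synthetic drug-like SMILES
mqn    <- compute_mqn(as.character(lib))           # 400 x 42 integer counts
cb     <- pq_codebook(mqn, seed = 1)
cb
#> Product-quantization codebook: 42-dim vectors -> 6 subspaces of dim 7, 256 codewords each
#>   code size: 6 bytes  (compression factor 7)
#>   trained with 20 Lloyd iterations, seed 1

codes  <- pq_encode(mqn, cb)                       # 6-byte codes
tables <- pq_sd_tables(cb)
fit    <- pq_kmeans(codes, k = 8, tables = tables, seed = 1)
fit
#> PQk-Means model: 8 centroids (8 populated on training data)
#>   5 iterations, objective 1.802e+04 -> 1.415e+04

assigned <- predict(fit, codes, tables)
comp     <- compact_clusters(fit, assigned)
reps     <- select_representatives(codes, comp$assignment, comp$model, tables)
head(reps, 3)
#>   cluster  id       sd
#> 1       1  34 1.732051
#> 2       2 187 2.000000
#> 3       3  75 2.236068
```

The objective trace is the per-iteration sum of squared SD to the
assigned centroids (non-increasing by construction); each
representative is the cluster member whose code sits closest to the
centroid, with its SD reported in MQN units. Sampled within-cluster
distances sit well below between-cluster distances:

```r
sample_cluster_distances(comp$assignment$label, "euclidean_mqn", x = mqn,
                         n_clusters = 5, n_per_cluster = 8, seed = 1)
#>          metric within_mean within_sd between_mean between_sd n_within n_between
#> 1 euclidean_mqn    6.957702  4.281172     15.45989   5.045763      140       640
```

For the full workflow — shuffling, sharded descriptor calculation,
encoding, clustering, representative selection and the nested atlas —
use the pipeline:

```r
cfg <- pipeline_config("library.smi", "out", k = 20, knn_k = 6, seed = 1)
res <- run_pipeline(cfg)
res$atlas          # validated nested atlas (primary + one map per cluster)
plot(res$atlas$primary)
```

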