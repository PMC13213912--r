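---
title: "Methods: product-quantized clustering and nested tree-maps for molecule libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: product-quantized clustering and nested tree-maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem and the model

Screening libraries built by combinatorial enumeration now reach
billions of molecules. Classical clustering and embedding tools fail
there for a structural reason: anything that touches pairwise
similarities — hierarchical clustering, similarity maps, t-SNE/UMAP on
fingerprints — scales at least quadratically, and even linear-scan
methods become memory-bound once every molecule carries a
multi-kilobyte fingerprint. `nestedtmap` follows a different route:
compress first, then cluster in the compressed domain, and only ever
draw maps whose size is about the square root of the library.

**Representation.** A molecule is a 42-dimensional vector of molecular
quantum numbers (MQN): non-negative integer counts of atom types, bond
types, polar groups and topological features. MQN is deliberately
low-dimensional and interpretable; it captures whole-molecule
composition and size trends well, and it is cheap enough to compute for
every molecule in a library. We use RDKit's published MQN
implementation through a batch subprocess interface, with no scaling or
centring afterwards — product quantization operates on the raw counts.

**Product quantization.** The vector **x** ∈ ℕ₀⁴² is split into
*m* = 6 contiguous subvectors of dimension 7 (42 must be divisible by
*m*; 6 balances compression against quantization resolution — smaller
*m* quantizes too coarsely, larger *m* lengthens the code with little
benefit for a 42-dimensional count descriptor). For each subspace *j* a
codebook C⁽ʲ⁾ of L = 256 codewords is learned by k-means on a training
subsample (greedy k-means++ initialization, Euclidean distance, a fixed
20 Lloyd iterations; empty clusters are re-seeded from the farthest
point). A molecule's code is the tuple (c₁,…,c₆) of nearest-codeword
indices; with L ≤ 256 each index fits one byte, so a molecule costs 6
bytes — a 7-fold compression of the 42-entry vector, and the reason a
billion-molecule code matrix fits in workstation RAM.

**Symmetric distance.** Precomputing the L×L matrices
Tⱼ[a,b] = ‖Cⱼ[a] − Cⱼ[b]‖² turns distance evaluation into table
lookups:

SD(a, b) = sqrt( Σⱼ Tⱼ[aⱼ, bⱼ] ).

We take the square root so SD is unit-compatible with Euclidean
distance on the raw MQN axis (the squared and rooted conventions are
equivalent for nearest-neighbour ranking; the rooted one makes the
SD-vs-Euclidean agreement plot a y = x comparison). SD is symmetric,
zero for identical codes, and *exact* — equal to the true Euclidean
distance — whenever both vectors coincide with their codeword
reconstruction.

**PQk-Means.** Clustering runs entirely in code space. Assignment uses
SD against the k centroid codes. The centroid update exploits that
squared SD decomposes additively over subspaces: for each cluster and
subspace, histogram the members' codeword indices, multiply the
histogram against Tⱼ to get the total squared distance from every
candidate codeword, and take the argmin. This per-subspace update is
the exact minimizer of the within-cluster squared-SD objective, so the
objective is non-increasing across iterations — the classical Lloyd
guarantee, preserved in the quantized domain. A user-specified k is a
deliberate design constraint: the primary map's size must be set a
priori, which rules out threshold-based methods whose cluster count
emerges from the data.

**Representatives and nested maps.** After streaming assignment, empty
clusters are dropped and labels re-indexed densely (at scale a
noticeable fraction of learned centroids ends up unpopulated; that is a
known property of the method, not an error). Each populated cluster is
represented by the member with minimal SD to the centroid. The primary
tree-map organizes representatives by MQN/Euclidean similarity; each
secondary tree-map organizes one cluster's members by ECFP4/Tanimoto
similarity. The two representations are complementary: MQN separates
composition and size regimes between clusters, ECFP4 resolves
substructural relationships within a cluster that a 42-count vector
cannot. A tree-map is: k-nearest-neighbour graph (k = 10 by default) →
minimum spanning tree → 2D tree layout.

# Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| m (subspaces) | 6 | — | must divide 42; compression/quality balance |
| L (codewords) | 256 | — | one byte per index; largest single-byte codebook |
| codebook iterations | 20 | Lloyd steps | fixed budget; convergence is effectively reached on count data |
| codebook sample | 5×10⁷ | molecules | training cost cap at scale; any n ≥ L works |
| k (clusters) | user-set (10⁵ at scale) | — | sets the primary map size a priori; ~√N for balanced nesting |
| fit iterations | 20 | Lloyd steps | early stop when labels stabilize |
| kNN k | 10 | neighbours | enough connectivity for a faithful MST without densifying the graph |
| ECFP4 length | 2048 | bits | standard folded length; configurable power of two |
| batch/shard size | 65,536 / 1,000 | molecules | bounds peak memory; results are bit-identical for any split |

All tie-breaks resolve to the lowest index (nearest codeword, nearest
centroid, codeword vote, representative), which makes every stage
deterministic given its seed.

# Numerical and design choices

* **Greedy k-means++.** Both initializers sample 2 + ⌊log k⌋ candidates
  from the D² distribution per step and keep the one minimizing the
  resulting potential. Plain D² sampling occasionally splits one true
  cluster and merges two others (a classical k-means local optimum);
  the greedy variant makes recovery of well-separated clusters robust
  across seeds.
* **Empty clusters.** During codebook training an empty codeword is
  re-seeded from the point farthest from its centre (quantizers should
  use all their codewords). During PQk-Means fitting an emptied
  centroid is left in place and flagged; compaction after the final
  assignment handles it. This mirrors how the method behaves at scale,
  where requested and populated cluster counts differ.
* **Disconnected kNN graphs.** Before MST extraction, components are
  joined through the minimum-distance inter-component pair found by
  exact search over component members, so every map is one tree with
  exactly n − 1 edges.
* **Layout.** The tree is rooted at its highest-degree node and drawn
  radially: radius = depth, angular wedges proportional to subtree leaf
  counts, plus a small seeded jitter confined to the wedge. Only
  topology and determinism are contractual; coordinates are
  presentation. Distinct nodes provably receive distinct coordinates
  (disjoint positive-width wedges; the root alone sits at the origin).
* **Shuffle stage.** Input lines are sorted canonically before the
  seeded permutation, so shard content is a pure function of the line
  multiset and the seed — libraries delivered pre-sorted (e.g. by heavy
  atom count) and arbitrarily ordered ones produce identical clusters.
* **Percentiles** use linear interpolation between order statistics
  (R's type 7). In dispersion statistics, clusters with zero mean for a
  descriptor are excluded from that descriptor's CV and counted,
  because CV = σ/μ is uninformative as μ → 0; IQR and range are
  reported alongside for exactly that reason.
* **Approximate kNN** (optional, Euclidean only) collects candidates
  from windows along 12 seeded random projections and scores them
  exactly. Exact mode is the reference contract; the approximate mode
  is assessed only by neighbour recall against exact (≥ 0.9 on test
  sizes). The Tanimoto metric has no approximate mode here.
* **Degenerate inputs.** Unparseable SMILES are flagged, counted and
  excluded, never fatal; single-member clusters yield one-node maps;
  duplicate molecules produce zero-weight edges and land adjacent in
  the tree.

# What the synthetic generators emulate — and what they do not

`generate_smiles_library()` enumerates scaffold × linker × terminal
combinations from a curated fragment grammar. Every combination is a
valid, drug-like (MW < 500) SMILES, and scaffolds span 0–4 rings so MQN
vectors form non-degenerate clusters. This emulates the *combinatorial*
character of make-on-demand libraries — shared scaffolds decorated with
small substituents — but not their chemistry: no reaction awareness, no
stereochemistry, no property filtering beyond construction, and heavy
duplication at large n (the grammar has ~4,400 distinct products).
Passing tests on this generator demonstrate the pipeline's mechanics
(compression fidelity, conservation, determinism), not chemical
coverage of any real vendor library.

`generate_mqn_blobs()` produces labelled 42-dimensional count vectors:
k integer centres rescaled so their minimum pairwise distance equals a
requested separation, members perturbed by rounded Gaussian noise
truncated at zero (centres are shifted away from zero so truncation is
essentially inactive). The expected within-blob distance to centre is
about spread·√42. Clustering-recovery tests use separation ≥ 5× that
within-blob scale; real MQN data is not blob-like, so these tests
establish correctness of the algorithm, not expected ARI on real
libraries.

# Problem sizes used in the shipped checks

The test suite and the acceptance script run at desk scale, chosen so
the full suite completes in a few minutes: oracle equivalences on
n ≤ 2,000; blob recovery at n = 10,000, k = 10; quantization fidelity
on a 20,000-molecule synthetic library; the end-to-end atlas on 2,000
molecules with k = 20. The at-scale configuration (k = 10⁵, codebook
sample 5×10⁷, billion-code streaming) is the documented default of
`pipeline_config()` but is exercised here only through its
scale-independent contracts: batch-size invariance, bounded per-stage
working sets, and manifest reconciliation.

# Known limitations

* MQN quantization resolution: with L = 256 per 7-dimensional subspace,
  molecules differing by less than the local codeword spacing receive
  identical codes; SD is then zero although the true distance is not.
  The SD-vs-Euclidean correlation quantifies this blur.
* The descriptor stage requires a Python/RDKit installation; R-side
  cheminformatics toolkits in common use do not implement MQN.
* Secondary maps are built eagerly by the pipeline; for very large k,
  on-demand construction (supported by calling `build_secondary()`
  directly) is the practical route.
* The radial layout optimizes nothing beyond topology; it will not
  reproduce the aesthetics of force-directed tree layouts used by
  interactive front ends.
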