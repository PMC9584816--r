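---
title: "Building and annotating hierarchical single-cell atlases with atlasforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and annotating hierarchical single-cell atlases with atlasforge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atlasforge)
```

# Scope

`atlasforge` covers the computational backbone of assembling a
multi-dataset single-cell reference of a heterogeneous tissue and putting
it to work: within-dataset batch discovery, a nested cluster tree with
statistically grounded markers and automatic names, spatial (ISH-voxel)
region inference, query-cell label projection, bulk-signature mapping, and
condition-dependent activation scoring. Everything runs on plain
`Matrix`-backed containers and is exercised end-to-end on seeded synthetic
data with planted ground truth.

Out of scope by design: read alignment and UMI counting, deep generative
integration models (the reference embedder is a pluggable contract with a
PCA default), doublet-score computation itself (per-cell calls are inputs),
UMAP layout, GO/motif enrichment, and any external database access.

# The data model

A `GeneMatrix` holds sparse integer counts (cells x genes) plus an optional
log-normalized layer, `log1p(count / total * 10^4)`. The 10,000 scale
factor is the droplet-toolkit convention; normalization never changes the
sparsity support, and a zero-total cell is an error that points the user at
`qc_filter` rather than silently producing `NaN`.

QC keeps cells with at least 1,000 UMIs and at most a 0.1 mitochondrial
fraction, both boundaries inclusive: a stated minimum keeps the minimum.
Doublet handling follows two rules: clusters with a doublet fraction
*strictly above* 0.7 are flagged for removal, and clusters whose cells score
high for two or more cell-class signatures (plain mean of signature-gene
log-normalized expression) are flagged for *manual review*, not deleted —
intermediate cell types are real.

Highly variable genes are ranked by standardized dispersion (variance of
the log-normalized values, z-scored within 20 mean-expression bins); ties
break lexicographically and zero-variance genes are never selected. PCA
fixes each component's sign so the largest-magnitude loading is positive,
making embeddings reproducible bit for bit.

# Batch detection

Within each dataset, samples start as their own groups. A probabilistic
classifier is trained to predict group labels from the 50-PC embedding and
its held-out class probabilities are summarized two ways:

* group dissimilarity: one minus the Spearman correlation of the groups'
  mean probability profiles (a constant profile gets distance 1 with a
  warning);
* separation: normalized entropy
  `H = mean_cells(-sum_i p_i log p_i) / log(n_groups)`, which is 1 at
  chance and 0 at perfect separation. A single group is defined to have
  `H = 1`, so a fully merged state is terminal.

The loop proposes merging the closest pair, retrains the classifier on
those two groups' cells only, and accepts the merge when their pairwise
entropy is at least 0.9 — the classifier cannot tell them apart, so they
are technical replicates of one batch. The wording of the procedure leaves
open whether the 0.9 gate applies to the candidate pair or to the global
average; we gate per candidate pair (matching "retrain only on the
currently merged samples") and expose the global variant behind
`gate = "global"`. Ties in closest-pair selection break lexicographically.

The shipped classifier is a leave-one-out k-NN class-probability estimator
(k = 25). The original procedure used random-forest out-of-bag
probabilities; that package is not among our dependencies, and the
classifier is deliberately a contract — any `(embedding, labels) ->
held-out probability matrix` function can be plugged in. A k-NN vote at
chance has expected normalized entropy well above 0.9 for balanced groups,
so the default threshold carries over.

# The cluster tree

Clustering runs on the shared nearest-neighbour graph (k = 25, Jaccard
edge weights over neighbour sets including self, edges below 1/15 pruned)
with Leiden community detection (igraph, modularity objective, fixed
seeds) over a resolution ladder. Level selection is greedy: starting from
the analyst-fixed base levels (in the motivating atlas, level 1 is a
manual neuron/non-neuron split), repeatedly pick the clustering whose
cluster count is closest to three times the previous pick.

Levels are reconciled into a strictly nested tree by attaching each finer
cluster to the coarser cluster holding the plurality of its cells (ties:
larger coarse cluster, then lexicographic) and rewriting every cell's
coarser labels from its finest label's ancestor chain. This is the
built-in fallback for published multiresolution-tree reconcilers, which
can be plugged in unchanged. Node ids are `C<levelsize>-<k>` with `k`
assigned by descending size; if two levels happen to have equal cluster
counts the later level's ids carry the level index (`C9.3-k`) so ids stay
unique.

Pruning merges over-split siblings: a node with fewer than 10 genes at
vs-sibling specificity above 1 (and adjusted p below 0.05) merges into its
most similar sibling by Spearman correlation of mean expression profiles.
We iterate to a fixpoint (a single-pass flag exists) because one merge can
change a neighbouring sibling set's markers; the merge target choice is
our own — the source procedure says only that weak siblings were merged.

# Marker statistics

Every node is tested against two references: all other cells at its level
*within its top-level subtree* (marker lists stay relevant by not
comparing, say, a neuron subtype against glia), and its sibling nodes.
The test is the stratified van Elteren rank-sum test with strata given by
dataset of origin: per stratum, the tie-corrected Wilcoxon statistic with
locally best weights `w_h = 1/(n_h + 1)`; strata lacking either group are
skipped; all-tied data return `z = 0, p = 1`. With one stratum this is
exactly the tie-corrected normal-approximation Mann-Whitney test, which is
the verification anchor in the test suite (agreement to `|dp| < 1e-10`
against the independent `wilcox.test` implementation).

Fold changes are computed on de-logged normalized means with pseudocount 1,
and specificity is

```
S = avg_log2FC * Pct_in / max(Pct_out, 1/n_ref)
```

with the reference detection fraction floored at one cell to avoid division
by zero. Multiple testing uses Bonferroni over the genes tested per
comparison. Genes detected in under 5% of both groups are not tested.

# Naming

Nodes are visited top-down. Candidates are the node's vs-sibling markers
passing the adjusted-p filter (0.05), minus excluded patterns (defaults
`^mt-`, `^Rp[ls]`) and genes already used in an ancestor's name. The
naming score is

```
T = S_all * S_siblings / max(1, max over children i of S_siblings(i))
```

The denominator penalizes genes that really mark one sub-branch. Two
readings of "the specificity for all children" are possible; we take the
per-gene maximum over children, the only dimensionally consistent one. Two
numerical choices are ours: a child in which the gene was untested
contributes 0 to the maximum, and the denominator is floored at 1 —
without the floor, a gene whose child specificities are all near zero
(typical for a good whole-node marker, since all children share it) would
be divided by noise; the floor also makes the leaf case (`denominator =
1`) continuous. Ties break by vs-all specificity, then lexicographically.
An only child adds no gene and inherits its parent's name; top levels can
be named manually via a config map.

# Region prediction

Within each ISH voxel, probes with positive energy are ranked (rank 1 =
highest energy, midranks for ties). For a node's high-specificity markers
(S > 4), the voxel enrichment is the median marker rank divided by the
voxel's expressed-probe count; a region's score aggregates its four most
enriched voxels and is subtracted from 1, so 1 means the markers dominate
the top ranks. The phrase "voxels with the highest median ranks" conflicts
with the accompanying gloss that scores near 1 indicate top-ranked
markers; we resolve in favour of the gloss (take the *most enriched*
voxels) and keep the literal reading behind `literal_top_rank = TRUE`.

The best region is assigned when its score exceeds 0.8. Dataset origin can
veto implausible assignments: scores are multiplied by the fraction of the
node's cells coming from datasets whose sampling region is compatible
(floored at 0.25 so spatial evidence is attenuated, not erased — the
original workflow did this step by manual curation).

# Projection

The reference embedder is a contract; the default projects query
log-normalized expression onto the reference PCA loadings after matching
and zero-filling genes (a warning reports the missing fraction). Latent
rows are L2-normalized so Euclidean distances satisfy `cos = 1 - d^2/2`
exactly — the only reading under which the similarity formula is an
identity. Similarities are clipped at zero before voting so weights stay
non-negative. Each query cell's k = 25 nearest reference cells vote,
giving `p(Y = y | cell) = sum_i 1(y_i = y) sim_i / sum_j sim_j`; argmax
ties go to the single nearest neighbour, and an all-zero similarity row
falls back to a uniform vote with a warning. No Gaussian smoothing is
applied. Probabilities are computed per tree level independently.

# Signature mapping (RBO)

Bulk IP-vs-input tables are reduced to a signature (adjusted p < 0.05,
positive log2FC, sorted by descending log2FC with lexicographic
tie-break) and compared to each cluster's marker ranking with extrapolated
rank-biased overlap for uneven lists:

```
RBO = (1-p)/p [ sum_{d=1..l} (X_d/d) p^d + sum_{d=s+1..l} X_s (d-s)/(s d) p^d ]
      + [ (X_l - X_s)/l + X_s/s ] p^l
```

where `s <= l` are the list lengths and `X_d` the overlap of depth-`d`
prefixes (the shorter list capped at `s`). Persistence defaults to
p = 0.98 (a top-weighted but not myopic horizon of ~50 ranks); the
implementation is incremental (O(l)) and is tested exhaustively against a
naive closed-form evaluation on all duplicate-free list pairs up to length
6 over a 4-symbol alphabet. Scores are reported absolutely and relative to
the best node at the level.

# Activation scoring and cross-modality comparison

Immediate-early genes are first filtered to a mid-frequency panel
(detected in more than `min_cells` and at most `max_cells` cells —
silent and near-ubiquitous genes carry no usable condition signal). Per
cluster, panel genes detected in at least 10% of cells in either condition
are tested fasted vs fed with the rank-sum test; Bonferroni uses the total
number of tests across the run (the stricter, toolkit-matching convention;
per-cluster correction is a flag). The activation readout is the fraction
of expressed IEGs significantly up-regulated.

Cross-modality comparison correlates cluster-mean log-normalized
expression between two matrices over clusters with at least 10 cells in
both. Genes enter if detected in more than 20% of cells of some cluster
*or* exceeding mean 0.2 in some cluster. Per-cluster correlations use the
cluster's vs-all markers with specificity above 0.25 and per-gene
cross-modality r above 0.3 — the per-gene r is computed first, which is
the only non-circular ordering. Zero-variance genes are reported missing,
never imputed.

# The synthetic world

The generators plant everything the pipeline is supposed to find. Defaults
were chosen once, for realism at desk scale, and are the conditions under
which the acceptance tests run:

* a balanced tree of depth 3, branching 3 (27 leaf types), 100 cells per
  leaf, 1,000 genes;
* library sizes lognormal around 2,500 UMIs, baseline expression lognormal
  with sd(log) = 2, giving realistic sparsity (most genes detected in a
  minority of cells);
* 10 unique markers per node, boosted 2^3 = 8-fold along the cell's
  ancestor path, negative-binomial counts with dispersion parameter 5.
  Marker genes draw their baseline from a lower lognormal (meanlog -0.5,
  sd 0.75): cell-type markers are not broadly expressed housekeeping
  genes, and this keeps their detection contrast informative;
* batch effects as per-gene 2^N(0, batch_sd) factors shared by the samples
  of a batch; doublets as halved sums of two random cells' counts (keeps
  counts integral); a fasting-like condition multiplying IEG means by
  2^effect in designated nodes;
* an ISH voxel grid mapping regions one-to-one onto leaves, with the home
  leaf's markers boosted (strictly descending, so the noise-free limit
  puts them at exactly ranks 1..m) over lognormal probe noise;
* bulk signatures as weighted mixtures of node expectation profiles with a
  3-vs-3 replicate t-test at log2 noise sd 0.15 (strong ribosome-capture
  contrasts yield sizeable significant gene sets; at sd 0 the table is the
  exact expectation with p = 0 for any non-zero fold change, since a
  t-test is undefined at zero variance);
* a second modality resampling counts with class-specific mean distortion.

What the world does *not* emulate — and therefore what a green test does
not establish — includes ambient RNA, cell-cycle structure, non-balanced
hierarchies, batch effects confounded with cell type, spatial
autocorrelation beyond region blocks, and zero-inflation beyond the NB
model; the second modality resamples only the nonzero count support, so
modality-specific dropout of entirely new genes is out of scope.

# Determinism and degenerate inputs

All generators run under a saved-and-restored RNG seed and are
byte-reproducible; Leiden and the reference classifier take fixed seeds.
Tie-breaks are specified everywhere a ranking feeds a decision
(lexicographic on gene or node ids). Degenerate inputs have defined
behaviour rather than NaN: single-column entropy is 1, all-tied tests
return p = 1, empty marker sets score RBO 0 with a warning, constant genes
yield missing correlations, and an empty QC result warns instead of
erroring.

# Known limitations

The default classifier's entropy scale matches the 0.9 threshold for
balanced groups; strongly unbalanced group sizes push the chance-level
entropy down and a stricter (or adaptive) threshold may be warranted.
`prune_tree` recomputes sibling markers per merge, which is quadratic in
the number of weak siblings; fine for trees of hundreds of nodes, slow for
thousands. The PCA projector is a deliberately simple stand-in for deep
integration embedders and does not correct batch effects — it should be
replaced via the `ReferenceModel` contract when mapping across strong
technical divides.
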