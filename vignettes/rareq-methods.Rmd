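---
title: "Detecting rare cell populations from kNN-graph topology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting rare cell populations from kNN-graph topology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rareq)
```

## The problem and the idea

Rare cell populations — cell types making up less than 1% of a profiled
tissue — are routinely absorbed into larger clusters by
modularity-style clustering, because their contribution to any global
objective is negligible.  What rare populations do have is a distinctive
*local* signature: in the k-nearest-neighbor (kNN) graph of a
low-dimensional embedding, cells of a genuinely distinct rare type pick
each other as nearest neighbors, forming a small near-clique whose edges
rarely leave the group.  rareq turns that observation into an
annotation-free clustering procedure that works on any embedding —
PCA from scRNA-seq counts, SVD from ATAC, weighted multimodal or spatial
panel embeddings produced elsewhere — since it touches nothing but
Euclidean distances in that space.

## The connectivity score Q

All edge queries run against a single `NeighborIndex`: per cell, the
`k.param - 1` (default 19) nearest other cells by ascending Euclidean
distance, equal distances ordered by ascending cell index.  A cell always
has a directed self-edge, and a directed edge to each cell on the prefix
of its list allowed by the budget of the query at hand.

For a cell $i$, let $S$ be the neighborhood made of $i$ and its $k-1$
nearest neighbors (default $k = 6$).  Each member of $S$ spends a budget
of $k$ directed edges — its self-edge plus its own $k-1$ nearest
out-edges — and

$$Q_i \;=\; \frac{\#\{\text{edges from } S \text{ landing in } S\}}{k \times k}.$$

$Q$ ranges between $1/k$ and $1$; structurally it can in fact never fall
below $(2k-1)/k^2$, because the center's $k$ edges and every member's
self-edge are internal by construction.  We report the looser published
bound and the tighter structural one side by side and test both; the
package does not "correct" the documented range.  A neighborhood that is
a true clique — every member's out-edges stay inside — saturates $Q = 1$.
The default $k = 6$ is deliberately small: the score must remain
informative for populations of only a handful of cells, and a larger $k$
would dilute a 10-cell clique with majority cells.  Edge membership is
tested against each member's *own* $k-1$ nearest out-edges, not against
the full-capacity graph; this is the only reading under which the
denominator $k \times k$ equals the number of edges actually counted, so
$Q \le 1$ is guaranteed.

The cluster-level analogue for a cluster $C$ of $n$ cells replaces the
budget with $k_{\mathrm{eff}} = \min(n, k.param)$ (the published
$n$-vs-20 rule at the default capacity 20) and normalizes by
$n \times k_{\mathrm{eff}}$:

$$Q_c \;=\; \frac{\#\{\text{edges from } C \text{ landing in } C\}}{n \times k_{\mathrm{eff}}} \in \left[\tfrac{1}{k_{\mathrm{eff}}},\, 1\right].$$

A consequence worth noting: a singleton cluster has $Q_c = 1$ exactly
(budget 1, only the self-edge), which makes singletons unmergeable under
the strict acceptance rule below.

## From scores to clusters

1. **Propagation.**  Every cell starts as its own cluster.  A cell
   adopts the label of the neighbor in its size-$k$ neighborhood with
   the highest $Q$, provided that $Q$ *strictly* exceeds its own; ties
   among equal-highest neighbors go to the smallest cell index, and a
   cell with no strictly better neighbor is a *waypoint* that keeps its
   own label.  Strictness matters: with equality-adoption, two equal-Q
   cells could swap labels forever.  Since the best-neighbor pointer
   strictly increases $Q$, the pointer graph is a forest rooted at the
   waypoints, and the iterative adoption has a unique fixed point —
   every cell carries its root waypoint's label — which we resolve by
   pointer doubling (the iteration cap, default 100, is a safety net
   only).
2. **Voting.**  Synchronous rounds of kNN majority voting (modal label
   over the cell and its `voteK - 1` nearest neighbors, ties keep the
   current label) clean up boundary cells connected to several clusters.
   `voteK` defaults to $k = 6$ because the procedure reuses the
   neighborhood-size symbol; the capacity-20 alternative is exposed as a
   parameter since the description is ambiguous on this point.
3. **Retention.**  Clusters whose *mean member* $Q$ strictly exceeds
   `qThreshold` (default 0.6) are frozen as rare populations; they take
   no further part in merging, as source or as target, and are not
   re-flagged afterwards.
4. **Merging.**  The remaining clusters are visited in ascending size
   (small fragments are the likeliest spurious ones), in repeated full
   passes until a pass performs no merge.  For a cluster $C$, the
   candidate partner $C_n$ is the non-rare cluster receiving the most
   directed out-edges from $C$'s members (full capacity `k.param`,
   self-loops excluded, ties toward the smaller id).  The merge is
   accepted iff $Q_c(C \cup C_n)$ strictly exceeds both $Q_c(C)$ and
   $Q_c(C_n)$, *and* the fraction of $C$'s total out-edge budget
   $|C|(k.param - 1)$ pointing at $C_n$ exceeds `ratioThreshold`
   (default 0.2).  The union takes the id of the larger constituent.
   Each merge reduces the cluster count, so termination is guaranteed.

Final cluster ids are contiguous integers from 0, largest cluster first.
Because singletons are structurally unmergeable ($Q_c = 1$), a
`minClusterSize` parameter (default 1 = strict behavior) optionally
force-assigns sub-threshold clusters to their most-connected non-rare
neighbor after the strict passes.

The core pipeline contains no randomness anywhere: identical input gives
byte-identical output, and permuting the cells permutes the output up to
label renaming whenever no exact distance ties exist.

### Behavior on diffuse data

On a homogeneous Gaussian cloud the local maxima of $Q$ are numerous, so
propagation plus voting yields many fragments, and the 0.2 edge-ratio
gate — a fragment inside a diffuse cloud spreads its out-edges over many
adjacent fragments, rarely concentrating 20% on a single one — means
most of them stay separate.  Rare-population calls are unaffected (the
rare clique is retained before merging, and fragments of the majority
are annotated to the majority type by any evaluation), but users should
not read the final number of *major* clusters as an estimate of the
number of major cell types in unstructured data.  The merge rule does
what it is designed to do when a genuine cluster has been artificially
split: the two halves of a bisected blob exchange roughly half their
edges, pass the ratio gate easily, and re-merge.

## Numerical choices

* **Exact kNN with a total order.**  Neighbor lists are computed exactly
  (a full scan below 2,049 cells; above that, BLAS-blocked candidate
  generation re-refined coordinate-wise, bit-identical to the scan) and
  ordered by ascending (squared distance, cell index).  Distances are
  accumulated coordinate-wise so that geometrically equal distances
  compare equal in floating point and the index tie-break actually
  fires; this is what makes collinear and symmetric fixtures
  reproducible to the bit.  Above an `exactThreshold` (default 50,000
  cells) an approximate kd-tree search is used and flagged in the
  result, a concession to million-cell atlases where an exact scan is
  wasteful.
* **Q equality.**  All score comparisons (propagation argmax, retention,
  merge acceptance) are exact floating-point comparisons; since every
  score is a ratio of small integers to $k^2$ or $n \, k_{\mathrm{eff}}$,
  equal counts give bit-equal scores and the strict/non-strict
  distinctions are well defined.
* **PCA determinism.**  Gene standardization clips at $\pm 10$ standard
  deviations (a common convention; the clip value is a parameter), and
  each component's sign is fixed so its largest-magnitude loading is
  positive, making embeddings reproducible across runs and gene orders.
* **Normalization base.**  "Log-normalization" uses natural log1p of
  scaled library-size fractions.  A monotone base change is *not*
  harmless downstream — PCA is not scale-free gene-wise — so the base is
  documented rather than assumed away; parity with any specific
  toolkit's matrix values is a non-goal, parity at the level of
  downstream cluster recovery is what the tests check.
* **HVG selection** ranks variance/mean dispersion of de-logged values,
  z-scored within 20 equal-frequency mean bins, ties by gene order —
  a deterministic, standard mean-variance standardization.

## The synthetic generators

The generators are first-class, tested code; they define the study
conditions under which the method's claims are checked.

* `makeBlobs()` plants isotropic unit-variance Gaussian types with
  centers `separation` apart along coordinate axes (so two centers are
  $\sqrt{2} \cdot$`separation` within-type standard deviations apart) —
  a stand-in for a real embedding with a known rare group.  Counts per
  type follow largest-remainder rounding.
* `simulateCounts()` is a gamma-Poisson simulator in the splatter
  tradition: Gamma gene base means (shape 0.6, rate 0.3), per-group
  log-normal DE factors (a gene is DE with probability `deProb`;
  log-factor mean 0.4, sd 0.8 by default; the sign of the log-factor is
  symmetric, since the fraction of down-regulated DE genes is a free
  choice), log-normal library sizes, Poisson counts on
  library-normalized group means.  It reproduces the *distributional
  essence* of that model, not any specific RNG stream: exact published
  cell splits or DEG counts from a particular simulator seed are
  explicitly not reproduction targets.  Only `outProb = 0` (no
  expression outliers) is implemented; nonzero values error rather than
  silently differ.
* `downsampleByType()` builds benchmark mixtures with an exact rare-cell
  quota (e.g. 50 rare cells in ~5,000) and majors in source proportions;
  `multiscaleSeries()` forces exactly `rareN` (default 10) rare cells at
  every scale; `degTitration()` replaces a nested random subset of
  null-data genes with pre-identified DEG columns so sensitivity curves
  are monotone by construction; `perturbUpregulate()` multiplies chosen
  genes by a fold change in target cells only.

What the blob model does **not** emulate: count noise reaching the
embedding through a preprocessing chain, unequal cluster densities and
anisotropy, batch structure, doublets or continuous trajectories.  The
count simulator restores the first of these but remains Poisson (no
extra biological coefficient of variation), with clean group labels and
no batch effects.  Passing the planted-recovery tests therefore shows
the inference engine does what it claims *under its own model
assumptions*; it does not certify performance on any real tissue.

## Test and verification design

Every score has an independent $O(n^2)$ brute-force oracle implemented
from the definitions (all-pairs distance sort, explicit set
intersection) that shares no code with the package; the suite checks
exact equality on 100+ random instances up to 60 cells, the analytic
extremes (a tight 6-clique has $Q = 1$; an isolated 10-cell cluster has
$Q_c = 1$), the range bounds on every generated instance, and scale
invariance.  The engine-level properties — rare-vs-majority $Q$
separation, planted-model recovery (median rare-type F1 = 1 over 20
seeds at high separation, collapse at separation 0), re-merging of a
bisected blob vs. non-merging of disconnected blobs, determinism and
permutation consistency — run on generated data at fixed seeds.  The
problem sizes used by the heavier checks (2,000-cell blob replicates;
titration on 1,500 cells by 2,000 genes with 10 repeats per level; a
multi-scale series of 1,000–50,000 cells at 1,500 genes with library
log-mean 9.2, i.e. ~10k UMIs per cell) were chosen as the smallest
instances that still exercise the regime each claim is about.
`scripts/acceptance.R` recomputes the analytic extremes from scratch
against the installed package.

## Known limitations

* Permutation invariance is conditional.  $Q$ takes at most
  $k^2 - 2k + 2$ distinct values, so equal-score ties are pervasive on
  real-sized data, and the smallest-cell-index tie-break makes fragment
  boundaries on large *diffuse* clouds depend on cell order.  Compact,
  well-separated populations are unaffected (the suite verifies
  label-level invariance there), and repeated runs on the same input are
  always byte-identical; but on unstructured data a cell permutation can
  shift a few boundary assignments.
* The strict $Q_c$ acceptance rule plus the adaptive budget make small
  fragments (and singletons especially) hard to merge; `minClusterSize`
  is the pragmatic escape hatch.
* Rare populations whose cells are *not* mutual nearest neighbors in
  the embedding (e.g. a rare type smeared along a trajectory) violate
  the clique premise and will not score high $Q$.
* Metrics: per-type F1/Jaccard use majority-type cluster annotation; a
  cluster counts toward a rare type only when annotated to *that* type.
  NMI uses the mean-entropy normalization with documented zero-entropy
  conventions (1 for identical set partitions, else 0).
* ATAC TF-IDF/SVD, multimodal WNN and other upstream embeddings are
  consumed, not produced: the package's preprocessing covers the
  counts-to-PCA path only.
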