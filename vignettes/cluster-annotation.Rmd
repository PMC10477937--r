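---
title: "Cluster-level reference-based annotation: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cluster-level reference-based annotation: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clustann)
```

## The problem

After clustering a single-cell RNA-seq dataset, each cluster needs a
cell-type label. Reference-based annotation borrows labels from an
already-annotated dataset by comparing expression profiles. `clustann`
does this at the *cluster* level: the only query input it needs is a
genes × clusters matrix of average log-normalized expression, which makes
annotation fast and memory-light, at the cost of ignoring per-cell
heterogeneity within a query cluster (a deliberate trade-off — if a
cluster mixes two cell types, the clustering, not the annotation, should
be refined).

The hard part of label transfer is not finding the best-correlated
reference cell type — it is deciding when the best match is still not
good enough. Two datasets never share a correlation scale: platform,
depth and composition shift the whole distribution. `clustann` therefore
calibrates a query-specific cutoff against a broad multi-tissue
*background* atlas, on the premise that most query-cluster /
background-cluster pairs are different cell types and thus sample the
"unrelated" part of the correlation distribution.

## Normalization

All profiles are pseudobulk: raw counts are summed over a cluster's
cells, divided by the cluster total, multiplied by a scale factor
(default 1e5) and transformed with `log(1 + x)`. Summing before
normalizing (rather than averaging per-cell normalized values) weights
cells by their depth and makes the back-transformed profile sum exactly
to the scale factor — an identity the tests exploit. The two orders
genuinely differ; the sum-then-normalize order is the package's
contract.

## Reference bundles

`build_reference()` turns an annotated counts matrix plus a background
atlas into the bundle `annotate_clusters()` consumes:

1. *Joint embedding.* Reference and background cells are embedded
   together. Any user embedding (CSV of per-cell coordinates) is
   accepted; the default is joint PCA with 30 components on
   library-size-normalized, log1p, per-gene standardized expression,
   computed through the cell–cell Gram matrix (cells ≪ genes at the
   scales this package targets). Deep generative integration tools fit
   the same contract — all downstream algebra needs is one coordinate
   per cell — so the embedding is pluggable; the bundle records which
   one was used.
2. *Joint clustering.* A k-nearest-neighbour graph (k = 15, Euclidean)
   with Leiden modularity communities (resolution 1) partitions all
   cells into combined clusters. Over-splitting here is harmless (the
   weight matrix re-aggregates); merging distinct types is what the
   resolution guards against.
3. *Correction.* `Eb` is the mean per-cell log-normalized expression of
   each combined cluster. `Wb[c, t]` is the fraction of cell type *t*'s
   cells in combined cluster *c*; columns sum to one. The corrected
   cell-type profile is the product `Er = Eb %*% Wb` — each cell type
   becomes the weighted average of the joint clusters it occupies, which
   places reference cell types and background clusters on a common
   expression scale.
4. *Sub-clusters.* Author labels often merge adjacent sub-types. Cells
   are re-clustered within each main type (same graph machinery,
   resolution 0.3); sub-cluster pseudobulks (`Er-sub`) carry ids
   `"<type>::<k>"` so the sub-to-main map is self-describing. Types with
   fewer than 10 cells are not split: singleton sub-clusters produce
   unstable correlation targets.
5. *Markers.* Marker specificity is the cosine between a gene's
   cross-cluster expression vector and the one-hot indicator of the
   cluster: `score(g, k) = e_gk / sqrt(sum_j e_gj^2)`. It is
   scale-invariant per gene, never NaN (all-zero genes score 0), and
   needs only cluster-level profiles. Ties are broken by higher
   expression in the target cluster, then gene id. The default of 50
   markers per cluster for all three sets (background, main, sub)
   balances specificity against the 30-shared-gene floor the
   correlation step enforces.

## The adaptive cutoff

Pooled correlation coefficients are decomposed into 1–3 univariate
Gaussians with unequal variances. The EM is deterministic: components
are initialized from contiguous blocks of the sorted data, run at most
200 iterations to a log-likelihood tolerance of 1e-8, with a small
floor on component standard deviations to prevent collapse; BIC picks
the component count. Determinism buys exact reproducibility and
translation equivariance (shifting all coefficients by δ shifts the raw
cutoff by δ), both covered by property tests; an independent EM
implementation (`mclust`) is used as a cross-check oracle in the suite.

The cutoff rules per selected component count:

- **k = 1** — everything looks like "different cell types"; the cutoff
  is the component's 0.75 quantile (μ + 0.674σ).
- **k = 2** — low component = different, high component = same; the
  cutoff is where the *weighted* densities intersect between the two
  means (the classification boundary), found by bisection to 1e-12. If
  the weighted densities do not cross between the means (one component
  dominating everywhere), the midpoint of the means is used and
  flagged.
- **k = 3** — the 0.75 quantile of the middle component. The
  "cumulative probability exceeds 0.75" rule is read at component
  level in both the k = 1 and k = 3 cases, for consistency.

The raw cutoff is clamped to [0.4, 0.6] (user-configurable
`--min-cutoff`/`--max-cutoff`); the clamp keeps a degenerate calibration
from making the screen vacuous or impossible. With fewer than 50 pooled
coefficients a mixture fit is unreliable, so the midpoint of the clamp
range is used and flagged (`fallback_used`) — visible in small worked
examples where a 5-cluster query meets a 5-sub-cluster reference.

Whether the two-component intersection should be weighted by mixing
proportions was an open choice; the weighted version was selected
because it is the Bayes classification boundary between the two
populations, which is what "this correlation is more likely drawn from
the same-type component" means operationally.

## The three modules

1. `module1_screen()` pools query × background correlations on
   background markers (the nq·nb coefficients), derives cutoff 1, and
   compares each query cluster's best correlation with `Er` (same
   marker set) against it. Clusters failing are finalized `unassigned`.
2. `module2_assign()` repeats the procedure on query × sub-cluster
   correlations with main-type markers (cutoff 2). No sub-cluster above
   the cutoff → `unassigned`; one above, or several that map to a single
   main type → assigned directly; otherwise the top three sub-clusters
   (by correlation, ties by id) go to module 3. Module 3 is invoked
   only when candidates span at least two distinct main types — if they
   agree, there is nothing to disambiguate.
3. `module3_resolve()` runs one-sided Wilcoxon rank-sum tests between
   every ordered pair of candidates on their sub-markers, restricted to
   the query cluster's expression vector. A gene on two candidates'
   lists is removed from both sides of that comparison (a shared marker
   cannot testify for either side). P-values are exact by enumeration
   when both groups have ≤ 10 genes (valid under ties) and use the
   normal approximation with tie and continuity corrections otherwise.
   Candidates are scored by the sum of −log10(p) over their own tests
   ("highest aggregate significance"); correlation breaks ties.
   Candidates with fewer than 5 usable markers are dropped; if fewer
   than two survive, the highest-correlation candidate wins with a
   warning and the record is attributed to module 2, since no test was
   run.

Pearson correlation on log-normalized values is used throughout — the
dominant convention for expression-profile matching; marker-restricted
correlations with fewer than 30 shared genes are refused outright, as
they almost always indicate a species mismatch or the wrong reference.

## Species handling

Species is called when a query's gene symbols overlap a human or mouse
symbol universe by strictly more than 50% (higher ratio wins when both
exceed; an exact tie withholds the call). Cross-species queries are
converted with one-to-one orthologs only — paralog families are dropped
entirely, because averaging paralogs fabricates expression — matching
case-insensitively while preserving the table's casing. Symbol
universes are user-supplied assets; the package ships none.

## The synthetic generator

`scenario_spec()` defines the study conditions used throughout the
tests: 5 cell types, 40 dedicated markers per type, 2000 genes, 50
cells per type, marker fold-change 8, platform noise SD 0.2 on the log
scale, scenarios 1–4 for the four query/reference overlap relations,
with the background an independent simulation of the base types plus
twice as many unrelated ones (a miniature multi-tissue atlas). Counts
are negative binomial (size 4) around log-normal gene means.

Two generator choices deserve explanation:

- *Per-type biological effect.* Each (gene, type) pair carries a
  log-normal factor (sdlog 1) on top of the shared baseline. Without
  it, "distinct" types that differ only in 40 of 2000 genes remain
  ~0.78-correlated even on marker genes — far above the 0.6 clamp
  ceiling, so no screen could ever reject them, and nothing like real
  distinct cell types, which diverge transcriptome-wide. Setting the
  effect and the marker fold to their null values (sdlog 0, fold 1)
  recovers a generator whose types are statistically indistinguishable,
  which the tests use as a negative control.
- *Dispersion.* The NB size of 4 (per-cell squared CV 0.25) is set so
  that pseudobulk halves of one type correlate above 0.98 on the CPM
  scale while distinct types stay below 0.9 — the reproducibility a
  well-powered pseudobulk profile should have.

What the generator does *not* emulate: dropout coupled to expression,
ambient RNA, doublets, batch structure within a dataset, or continuous
differentiation trajectories. Passing the scenario suites therefore
shows the algorithm recovers well-separated discrete types under
overdispersed counts and platform noise — not that it resolves
continuum biology or contaminated libraries.

## Problem sizes and runtime

The test suite runs the full pipeline (simulate → build reference →
annotate → evaluate) on scenario 1 and scenario 4 for seeds 1–10 at the
default conditions above (1500 cells and 2000 genes per run), plus
self-annotation checks; the whole suite completes in well under a
minute on one CPU. These sizes were chosen as the smallest at which the
mixture calibration sees a representative correlation distribution
(≥ 50 pooled coefficients per module at 5 query clusters).

## Known limitations

- One query cluster receives one label; mixed clusters are not flagged.
- The background must be diverse for the calibration premise (most
  pairs unrelated) to hold; a background from a single tissue will
  push the cutoff toward the clamp floor and over-assign.
- Multiple references are evaluated independently, side by side; the
  package deliberately offers no consensus vote across references,
  since reference quality and nomenclature are not commensurable.
- Exact-symbol matching only; gene-alias resolution tables are a
  possible extension.
- Labels are compared verbatim at evaluation time unless a synonym
  table is supplied; the "partially correct" category is entirely
  user-defined (coarse/fine pairs) and unused by default.
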