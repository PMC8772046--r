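---
title: "Low-rank representation with a truncated nuclear norm and graph regularization: model and methods"
author: "tglrr package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Low-rank representation with a truncated nuclear norm and graph regularization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tglrr)
```

## The model

Tumor gene-expression cohorts that merge several cancer types are well
described by a *union of subspaces*: samples of each type lie near their
own low-dimensional linear subspace of the (very high-dimensional) gene
space.  Low-rank representation (LRR) methods expose that structure by
writing each sample as a linear combination of all samples.  The model
implemented here decomposes an expression matrix $X \in \mathbb{R}^{m
\times n}$ (genes $\times$ samples) as

$$X = XZ + GX + P,$$

where $Z \in \mathbb{R}^{n\times n}$ is the sample-space representation
(its columns carry the subspace membership used for clustering), $G \in
\mathbb{R}^{m\times m}$ is a feature-space component (its rows score
genes), and $P$ collects sparse gross errors.  The fitted objective is

$$\min_{Z,G,P}\;\; \|Z\|_r \;+\; \|G\|_* \;+\;
\frac{\beta}{2}\,\mathrm{Tr}(Z L Z^{\top}) \;+\; \lambda \|P\|_1
\quad \text{s.t.}\quad X = XZ + GX + P ,$$

with three ingredients:

* **Truncated nuclear norm** $\|Z\|_r = \sum_{i>r}\sigma_i(Z)$: only the
  singular values beyond the $r$ leading ones are penalized, so the
  dominant directions of the representation are not shrunk.  It is
  handled through the surrogate $\|Z\|_r = \|Z\|_* - \max_{AA^\top = I,
  BB^\top = I}\mathrm{Tr}(A Z B^\top)$, whose maximizing $(A, B)$ are the
  leading singular vector pairs of $Z$ (`top_r_factors()`).
* **Graph-Laplacian penalty** $\mathrm{Tr}(Z L Z^\top) = \tfrac12
  \sum_{ij} w_{ij}\|z_i - z_j\|^2$: representations of samples that are
  k-nearest neighbours in expression space are pulled together,
  preserving local manifold structure.  $W$ is the binary symmetric kNN
  weight matrix ("i near j *or* j near i"), $L = O - W$ with degree
  matrix $O$.
* **Entrywise $L_1$** on $P$: occasional gross measurement errors are
  absorbed without inflating the low-rank parts.

## The solver

The optimization alternates two procedures (`tglrr()`):

1. **Factor refresh.** $(A, B)$ are recomputed from the SVD of the
   current $Z$.  Singular pairs with numerically zero singular value are
   dropped: they leave the surrogate value unchanged but would otherwise
   inject an arbitrary subgradient direction into the next step (this is
   also what makes the all-zero matrix an exact one-iteration fixed
   point).
2. **One LADMAP sweep.** With a splitting variable $F$ ($Z = F$ carries
   the surrogate term) and multipliers $Y^1, Y^2$, each block is updated
   by a linearized proximal step: singular value thresholding for $Z$
   and $G$, a closed-form stationary point for $F$
   ($F = Z + (A^\top B + Y^2)/\mu$), and elementwise soft-thresholding
   for $P$.  Then the penalty $\mu$ grows by $\rho_0$ whenever the
   weighted iterate changes fall below $\varepsilon_2$, and the
   multipliers take a gradient step with the updated $\mu$.

The update order is $Z, G, F, P$, then $\mu$, then $Y^1, Y^2$.  A
single sweep per factor refresh is the default; `inner_sweeps` in
`tglrr_control()` runs several LADMAP sweeps per refresh, approximating
a two-loop scheme.  Iteration stops when both relative feasibility
residuals, $\|X - XZ - GX - P\|_F/\|X\|_F$ and $\|Z - F\|_F/\|X\|_F$,
fall below $\varepsilon_1$.

Two printed-formula corrections are deliberate design choices: the $F$
update is the exact stationary point of its subproblem (the multiplier
must be scaled by $1/\mu$ and the factor term is $A^\top B$), and the
$G$ gradient uses $Y^1$, the multiplier of the constraint it derives
from.  Since $L$ is symmetric, $\tfrac{\beta}{2}(ZL^\top + ZL)$ is
computed as $\beta Z L$.

### Monitored loss

The augmented-Lagrangian iterates start at zero, where the raw
objective is $0$ and necessarily rises as the constraint is enforced.
Convergence is therefore monitored (and plotted by `autoplot()`)
through the *loss*: the objective with the $L_1$ term evaluated on the
actual reconstruction error $X - XZ - GX$.  It starts at
$\lambda\|X\|_1$-scale and decreases to the final objective value; the
`history` tibble records both, together with both residuals, $\mu$ and
the change statistic.

## Parameters

| parameter | default | meaning / why |
|---|---|---|
| `lambda` | 0.01 | weight of the sparse error; $10^{-2}$ is the most common grid-search optimum for this model family and behaves well on the bundled synthetic conditions.  Larger values force structure out of $P$ into $XZ + GX$; the gene-selection workflow in the tests uses $\lambda = 0.5$ for exactly that reason. |
| `beta` | 0.1 | graph weight.  On desk-scale synthetic data with $n \approx 200$ the kNN graph mixes clusters when $\beta$ is large, so a small default is used; on real cohorts the grid search (`tglrr_grid_search()`) should choose it. |
| `r` | from `suggest_r()` | truncation level; the first inflection of the singular-value curve of $X$, automated as the argmax of the second difference over the first 20 values.  An explicit `r` always overrides. |
| `k_graph` | 5 | kNN neighbour count, the standard choice for graph-regularized factorizations; Euclidean metric by default, cosine available. |
| `mu0`, `mu_max` | $10^{-2}$, $10^{10}$ | initial and maximal penalty, the usual LADMAP span. |
| `rho0`, `eps2` | 1.9, 10 | penalty growth.  The growth test multiplies the iterate changes by the linearization constants $\eta_1 \approx \mu\|X\|_2^2$, so on unit-scale data the product is $O(1)$–$O(10^2)$; with much smaller `eps2` the penalty freezes near `mu0`, the $F$ update $(A^\top B + Y^2)/\mu$ blows up and the solver stalls.  The chosen pair makes growth engage from the start and reproduces the few-dozen-iteration convergence this model family reports. |
| `eps1` | $10^{-6}$ | relative feasibility tolerance; the bundled studies use $10^{-3}$. |

## Clustering and gene selection

`cluster_samples()` runs seeded K-means repeatedly and
`aggregate_runs()` reports mean and population variance of accuracy
(best label bijection via the Hungarian algorithm on the contingency
table), max-normalized mutual information (defined as 0 when either
partition has zero entropy) and the pairwise F-measure (precision and
recall over sample pairs; 0 when no pair is predicted together).

By default the samples are embedded in the `n_clusters` leading
eigenvectors of the symmetrized affinity $(|Z^*| + |Z^{*\top}|)/2$
before K-means — the standard spectral reading of an LRR affinity.  The
design was genuinely open here (one can also cluster raw columns of
$Z^*$, available as `affinity = "columns"`): on synthetic
union-of-subspace data the signed raw columns place points of one
subspace on opposite rays, which K-means' spherical clusters cannot
join, and no weight setting brought raw-column accuracy near the
spectral variant's, so the spectral embedding is the default.  Each
K-means run takes the best of `nstart = 10` seeded starts; single-start
runs fail a noticeable fraction of the time even on perfectly
block-structured affinities, which is initialization noise rather than
a property of the representation.

`score_genes()` ranks gene $i$ by $\|(G^* X)_{i\cdot}\|_2$, its
contribution to the feature component of the reconstruction (row norms
of $G^*$ alone are available as an option).  Ties break by row index.

## The synthetic generator

`simulate_subspace_data()` draws, per class, a random orthonormal basis
of the requested dimension and standard-normal coefficients, giving a
clean matrix whose rank is the sum of subspace dimensions; it then adds
(i) salient genes — rows with a constant $\pm$`salient_scale` offset
shared by all samples, a marker-like elevation that a feature-space
component can represent (a per-entry random pattern would be
statistically indistinguishable from gross corruption and would
correctly end up in $P$ instead of $G X$); (ii) dense Gaussian noise;
and (iii) exactly `round(corruption_frac * m * n)` entries replaced by
$\pm$`corruption_scale`.  Unbalanced class sizes are supported to
mirror integrated cohorts.  Everything is reproducible from one seed.

The generator emulates the *geometry* low-rank representation assumes —
linear subspaces, dense noise, sparse outliers.  It does not emulate
counts or intensities (no negative-binomial sampling, no
heteroscedasticity), batch effects, or correlated gene modules within a
class.  Tests passing on these fixtures therefore demonstrate that the
optimization and the evaluation stack behave as designed, not that the
method will separate any particular real cohort.

`pca_reduce()` reproduces the usual preprocessing: genes are centered
(PCA requires it; a `log2(x+1)` toggle exists for intensity-scale
data), samples act as observations, and the gene dimension is projected
onto the top principal directions, capped at the numerical rank.

## Study sizes and numerical choices

The bundled studies use 3 classes $\times$ 60 samples on 4-dimensional
subspaces in 200 gene dimensions (clustering), 3 $\times$ 20 samples in
100 dimensions with 5 planted salient genes (gene selection), and
40–60-sample instances for the convex-reduction and determinism checks
— sizes at which a full run takes seconds while every rank and
cardinality in play stays far from degenerate.

Other numerical decisions: all iterates initialize at zero (standard
LADMAP practice, and what makes $X = 0$ a fixed point); singular-vector
sign indeterminacy is resolved by making the largest-magnitude entry of
each left singular vector positive and flipping the paired right vector
with it, so results are reproducible and the trace identity is exact;
distance ties in the kNN graph break by column index; a non-converged
run returns `converged = FALSE` with its history rather than throwing,
while non-finite iterates throw with the iteration index.  With $X = 0$
the $G$ subproblem is degenerate ($\eta_2 = 0$) and the iterate is kept.

## Limitations

* LADMAP with an aggressive penalty schedule reaches feasibility fast
  but is not monotone in the residual, and the attained objective of
  the convex special case ($r = 0$, $\beta = 0$) can differ by a few
  percent between schedules at loose tolerances; tighten `eps1` when
  objective values themselves are of interest.
* Dense $n \times n$ and $m \times m$ SVDs bound practical sizes to a
  few thousand samples/genes; use `pca_reduce()` first on larger data.
* `suggest_r()` automates a visual inflection-point rule; on curves
  without a clear elbow it returns 1, and a user-chosen `r` is
  preferable.
* The defaults for `lambda` and `beta` are starting points; on real
  cohorts both should come from `tglrr_grid_search()`, whose optima are
  known to vary by orders of magnitude between datasets.
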