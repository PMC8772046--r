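# tglrr

Subspace clustering and feature-gene selection for gene-expression
matrices via **T**runcated-nuclear-norm and **G**raph-Laplacian
regularized **L**ow-**R**ank **R**epresentation.

## The problem

Integrated tumor cohorts — expression matrices that merge samples from
several cancer types — are well modelled as a *union of low-dimensional
subspaces*: each tumor type spans its own few-dimensional linear
subspace of the gene space.  Recovering that structure answers two
questions at once: *which samples belong together* (tumor clustering)
and *which genes drive the decomposition* (feature-gene selection).
This package is for computational biologists and methods researchers
who want a self-contained, scriptable implementation of that model with
its solver, evaluation indices and a synthetic data generator for
validation.

## The model

Given an expression matrix $X \in \mathbb{R}^{m\times n}$ (genes
$\times$ samples), solve

$$\min_{Z,G,P}\; \|Z\|_r + \|G\|_* +
\frac{\beta}{2}\mathrm{Tr}(Z L Z^{\top}) + \lambda \|P\|_1
\quad \text{s.t.}\; X = XZ + GX + P,$$

where $\|Z\|_r = \sum_{i > r} \sigma_i(Z)$ is the truncated nuclear
norm (the $r$ leading singular values go unpenalized, a tighter rank
surrogate than the nuclear norm), $L$ is the Laplacian of a k-nearest-
neighbour graph over samples (the penalty keeps representations of
neighbouring samples close), and $P$ absorbs sparse gross errors under
an entrywise $L_1$ penalty.  The problem is solved by a linearized
alternating-direction method with adaptive penalty (LADMAP) that
alternates an SVD refresh of the truncated-norm factors with proximal
block updates of $Z$, $G$, a splitting variable $F$, and $P$.

Clustering runs seeded K-means on a spectral embedding of the affinity
$(|Z^*| + |Z^{*\top}|)/2$ and is scored by accuracy (optimal label
assignment), normalized mutual information and pairwise F-measure;
genes are ranked by the row norms of the feature component $G^* X$.
See the methods vignette (`vignettes/tglrr-methods.Rmd`) for the full
account, including every numerical design choice.

## Worked example

Simulate three tumor-like classes (60 samples each on 4-dimensional
subspaces among 200 genes, dense noise plus 1% gross corruption), fit,
cluster, and rank genes:

```r
library(tglrr)

sim <- simulate_subspace_data(n_clusters = 3, subspace_dim = 4,
                              samples_per_cluster = 60, ambient_dim = 200,
                              noise_sigma = 0.05, corruption_frac = 0.01,
                              seed = 0)
fit <- tglrr(sim$X, control = tglrr_control(eps1 = 1e-3, max_iter = 500))
fit
#> TGLRR fit: 200 genes x 180 samples | lambda = 0.01, beta = 0.1, r = 12, k = 5
#> converged after 57 iterations (residual 0.000972, objective 21.6136)

evaluate_clustering(fit, sim$labels, n_runs = 10, seed = 1)
#> Clustering evaluation over 10 run(s):
#>   acc       1.0000 +/- 0.0000
#>   nmi       1.0000 +/- 0.0000
#>   f_measure 1.0000 +/- 0.0000

head(score_genes(fit$G, sim$X), 3)
#> # A tibble: 3 x 4
#>   gene_id  score  rank   row
#>   <chr>    <dbl> <int> <int>
#> 1 gene_92  0.389     1    92
#> 2 gene_153 0.375     2   153
#> 3 gene_47  0.366     3    47
```

The fit line says the solver reached both feasibility constraints
(relative residual below the 1e-3 tolerance) in 57 iterations, with the
truncation level `r = 12` read automatically off the singular-value
curve of `X` (the data's true rank is 3 × 4).  The evaluation block
reports mean ± variance of each index over 10 seeded K-means runs — all
1.0 here, i.e. the planted three-class partition is recovered exactly.
The gene table is the top of the ranking by contribution to the feature
component `G X` (no salient genes were planted in this simulation, so
these are ordinary genes with the strongest feature-space signal).

`tidy(fit)` returns the per-iteration history as a tibble,
`glance(fit)` a one-row summary, and `autoplot(fit)` the convergence
curves.  `run_pipeline()` drives simulate → PCA → fit → cluster →
evaluate → select-genes from a YAML/JSON config and writes delimited
artifacts; `inst/cli/tglrr-cli.R` exposes the same stages as shell
subcommands (`simulate`, `pca`, `fit`, `cluster`, `evaluate`,
`select-genes`, `grid-search`, `suggest-r`, `run`).

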