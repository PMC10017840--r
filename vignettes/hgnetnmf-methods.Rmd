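---
title: "Methods: hypergraph-regularized network tri-factorization"
author: "hgnetnmf authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hypergraph-regularized network tri-factorization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hgnetnmf)
```

## The problem

Imaging-genetics studies measure two feature sets on the same subjects —
for example gray-matter volumes of brain regions of interest (ROIs) and
gene expression — and ask which *groups* of features in one modality move
together with which groups in the other. `hgnetnmf` addresses this by
jointly factorizing three association networks:

* $R_{11} \in \mathbb{R}^{p \times p}$: associations among the $p$ ROI
  features,
* $R_{22} \in \mathbb{R}^{q \times q}$: associations among the $q$ gene
  features,
* $R_{12} \in \mathbb{R}^{p \times q}$: cross-modality associations,

all built as Pearson correlations made non-negative (see below). The model
is the joint non-negative tri-factorization

$$\min_{G_1, G_2, S_{11}, S_{22} \ge 0}
  \|R_{11} - G_1 S_{11} G_1^\top\|_F^2 +
  \|R_{12} - G_1 G_2^\top\|_F^2 +
  \|R_{22} - G_2 S_{22} G_2^\top\|_F^2 +
  \lambda_1 \operatorname{tr}(G_1^\top L_1 G_1) +
  \lambda_2 \operatorname{tr}(G_2^\top L_2 G_2),$$

where $G_1 \in \mathbb{R}^{p \times k}$ and $G_2 \in \mathbb{R}^{q \times k}$
hold $k$ paired modules in their columns (column $j$ of $G_1$ and column
$j$ of $G_2$ are coupled through the $R_{12}$ term), and $S_{11}, S_{22}$
absorb within-modality module-module interactions. With
$\lambda_1 = \lambda_2 = 0$ the model is the plain network tri-factorization
(netNMF); the trace penalties are the hypergraph-regularized extension.

## Hypergraph regularization

A hypergraph generalizes a graph by letting one edge (a *hyperedge*)
connect any number of vertices, which captures neighbourhood-level rather
than pairwise structure. We build one hyperedge per feature: the feature
plus its $k$ nearest neighbour features by Euclidean distance between
their profiles across samples (`feature_hypergraph()`). With incidence
matrix $H$, unit hyperedge weights $W$, vertex degrees
$d(v_i) = \sum_j w_j H_{ij}$ and hyperedge degrees
$\delta(e_j) = \sum_i H_{ij}$, the similarity and Laplacian are

$$S = H W D_e^{-1} H^\top, \qquad L = D_v - S.$$

$L$ is symmetric positive semidefinite and annihilates constant vectors,
so $\operatorname{tr}(G^\top L G)$ penalizes factor columns that vary
sharply across hyperedge neighbourhoods — it pulls features that share
neighbourhoods into the same modules.

Two conventions worth noting, both asserted by the test suite:

* the centroid feature is always a member of its own hyperedge, so every
  hyperedge has exactly $k + 1$ members;
* with $k = N - 1$ every hyperedge is the full vertex set and the closed
  forms $S = \mathbf{1}\mathbf{1}^\top$, $L = N I - \mathbf{1}\mathbf{1}^\top$
  follow directly from the definitions above.

Distance ties at the $k$-th neighbour are broken toward the lowest feature
index, making the construction deterministic across platforms. Distances
use raw (unstandardized) feature columns by default; `standardize = TRUE`
is available when the two modalities' scales differ wildly within a
matrix.

## Optimization

The objective is minimized by element-wise multiplicative updates derived
from the KKT conditions, applied in the order $S_{11}$, $S_{22}$, $G_1$,
$G_2$:

$$S_{11} \leftarrow S_{11} \odot
  \frac{G_1^\top R_{11} G_1}{G_1^\top G_1 S_{11} G_1^\top G_1 + \epsilon},
\qquad
G_1 \leftarrow G_1 \odot
  \frac{2 R_{11} G_1 S_{11} + R_{12} G_2 + \lambda_1 S^{(1)} G_1}
       {2 G_1 S_{11} G_1^\top G_1 S_{11} + G_1 G_2^\top G_2 +
        \lambda_1 D_v^{(1)} G_1 + \epsilon},$$

and symmetrically for $S_{22}$ and $G_2$. Three numerical choices matter:

* **Laplacian split.** Writing the penalty gradient with $L$ itself would
  place a signed matrix in the denominator and could produce negative
  factor entries. We use the standard graph-regularized-NMF split of
  $L = D_v - S$: the non-negative similarity part joins the numerator and
  the non-negative degree part the denominator. The fixed points are
  unchanged and every iterate stays non-negative.
* **Symmetric $S$ blocks.** $S_{11}$ and $S_{22}$ are initialized as
  symmetrized uniform draws; the updates then preserve symmetry exactly,
  which is the regime in which the simplified gradient (and hence the
  update rule) is exact.
* **Guard and initialization.** An $\epsilon = 10^{-10}$ guard is added to
  every denominator, and all factors are initialized from a seeded
  uniform$(0,1)$ draw — never at zero, which is an absorbing state of
  multiplicative updates.

Monotone descent of the full regularized objective is not proven here for
the quartic $G$ terms (the plain-ratio update is used, not a damped or
square-root variant); the suite instead checks it numerically on hundreds
of random instances across the $\lambda$ grid, with a $10^{-8}$ relative
slack, and has never observed a violation. Convergence is declared when
the relative objective change drops below `tol` (default $10^{-6}$) or
after `max_iter` (default 500) sweeps; both are configurable and neither
is a statement about when the objective truly plateaus — near-exact
recovery of noise-free low-rank networks takes several thousand sweeps at
`tol = 0`, which is what the exact-recovery test does.

## Making correlations non-negative

`association_networks()` offers two constructions:

* `method = "absolute"` (default): $R = |r|$. A strong negative
  correlation is treated as strong association. This is the natural choice
  when modules are defined by co-variation regardless of sign.
* `method = "truncate"`: $R = \max(r, 0)$. Negative correlations are
  treated as absent.

The choice changes the spectrum of the resulting networks materially: for
weakly correlated (noise-dominated) data, $|r|$ has a large common mean
component that a low-rank factorization captures easily, while truncation
zeroes half the entries and leaves relatively more unstructured mass, so
relative reconstruction errors are systematically higher under
truncation at the same rank. When comparing reconstruction errors across
studies, the construction must therefore be matched; results computed
under one convention are not comparable to results computed under the
other. The package default is `"absolute"`; every built-in protocol uses
it unless told otherwise.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `rank` ($k$) | `suggest_rank()` | module count; heuristic: $\max(2, \lfloor \min(n, p, q)/10 \rfloor)$ |
| `lambda1`, `lambda2` | selected | penalty weights; grid $\{10^{-4}, 10^{-3}, 10^{-2}, 10^{-1}\}$ searched exhaustively by `select_lambdas()` |
| `k1`, `k2` | selected | hyperedge neighbour sizes; searched by `select_knn_sizes()` |
| `threshold` | 1 | module membership: column z-score strictly above 1 |
| `min_size` | 5 | modules with fewer members on either side are dropped |
| PCC threshold | 0.9 (or `"mean"`) | edge rule (strict $>$) for the within-module interaction networks |
| `max_iter`, `tol` | 500, $10^{-6}$ | convergence control |

Selection runs sequentially — neighbour sizes first at fixed small
$\lambda$, then $\lambda$ at the chosen neighbour sizes — which bounds the
cost at the price of ignoring interactions between the two grids; a joint
search is a straightforward loop over `select_knn_sizes()` if needed.
Ties in every argmin are broken toward the smaller parameter value, for
parsimony. Module membership uses the population (divide-by-$N$) standard
deviation and a strict inequality; a constant factor column is flagged
degenerate and yields no members rather than NaNs.

## Module scoring and hubs

Each retained module is scored by the relative Frobenius error of the
reconstructions restricted to its member rows and columns — computed for
the ROI submatrix of $R_{11}$, the gene submatrix of $R_{22}$, the cross
submatrix of $R_{12}$, and their combined total. The module with the
smallest total is the *significant module*. Inside it, interaction
networks are built by thresholding the association submatrices (strict
$>$; threshold either fixed or the mean off-diagonal association), and
nodes are ranked by Maximal Clique Centrality,
$\mathrm{MCC}(v) = \sum_{C \in M(v)} (|C| - 1)!$ over the maximal cliques
$C$ containing $v$, enumerated with pivoting Bron–Kerbosch. A node whose
maximal cliques are all single edges scores its degree; an isolated node
scores 0. The suite verifies MCC against brute-force subset enumeration
on hundreds of random graphs.

## The simulation generator

`simulate_paired_data()` emulates a single shared latent factor: a sample
factor $\varepsilon \sim N(0, 1)$, weight vectors $u$ (ROIs) and $v$
(genes) with standard-normal entries, and additive Gaussian noise of
standard deviation $\sigma$ (the *noise level*). A fraction
`frac_correlated` (default 0.5) of the columns in each modality is
signal-bearing, $X_{\cdot j} = u_j \varepsilon + e$; the rest are pure
noise. Where the generative design left choices open we fixed them once:
all latent draws are standard normal (the simplest scale convention — only
the ratio of $u_j$ to $\sigma$ matters), the noise level is interpreted as
the noise *standard deviation*, and the signal-bearing columns are the
leading block, with their indices recorded in the returned truth object.

What the generator does *not* emulate: spatial autocorrelation of imaging
features, block co-expression structure beyond the single factor,
heavy-tailed expression noise, or sample covariates. Passing tests
therefore demonstrate correctness of the algorithms under a clean
one-factor model, not performance on real imaging-genetics data.

The packaged simulation study (`simulation_study()`, also driven by
`scripts/acceptance.R`) fits both the regularized model and the netNMF
baseline from matched seeds across noise levels, with the regularization
weight selected per noise level on the diagonal of the grid (the two
modalities are exchangeable in this design) on the first replicate and
then held fixed. The study sizes used by the packaged scripts are
$n \in \{300, 1000\}$ samples, $p = 200$ ROI features and $q = 500$ gene
features — the gene dimension is a deliberate desk-scale choice that keeps
a full sweep affordable on one core while leaving the error scale
comparable; the generator itself handles $q = 2000$ directly if a
full-scale run is wanted.

## Known limitations

* Dense algebra throughout; feature counts beyond a few thousand per
  modality will be slow and memory-hungry.
* The descent property of the plain-ratio multiplicative updates is
  empirical, not proven, for the quartic terms.
* The rank heuristic is a ceiling rule, not a model-selection criterion;
  stability- or cross-validation-based rank choice is out of scope.
* Maximal-clique enumeration is exponential in the worst case; MCC is
  intended for module-sized (tens to a few hundred nodes) networks.
* The relative-error normalization pools all three matrices; the
  `per_matrix` option changes the scalar and hence, potentially, the
  argmin of parameter selection.
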