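---
title: "Methods: cell-specific networks, weighted PageRank importance, and structural entropy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cell-specific networks, weighted PageRank importance, and structural entropy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cense)
```

# Overview

`cense` turns a single-cell expression matrix into one gene network per
cell, ranks genes inside each network by an expression-weighted random
walk, and summarises network complexity by the Shannon entropy of the
degree distribution. This vignette documents the model, every tunable
parameter, the numerical choices made where the underlying method leaves
room, and what the synthetic-data generator does and does not emulate.

# Preprocessing

The pipeline expects a genes × cells matrix of non-negative values with
per-cell `age_group` and `cell_type` labels. `preprocess_gem()` scales
each cell's counts to a common library-size target (default 10 000) and
applies `log(1 + x)`. Both the target and the log base are exposed
because neither is dictated by the method itself; the defaults are the
prevailing single-cell convention. Cells with zero total counts are kept
unscaled rather than dropped — quality control is assumed to have
happened upstream, and silently removing cells would change the cell
universe that all later per-cell structures are keyed on. The transform
is monotone within each cell, which matters because the network stage
only consumes within-gene expression rankings. A second call to
`preprocess_gem()` is an error, never a silent re-transform.

# Cell-specific networks

## The statistic

For cell $k$ and genes $i, j$, two neighborhoods each hold the
$m = \mathrm{round}(0.1\, n_C)$ cells whose expression of the respective
gene is nearest to cell $k$'s value. With overlap $n_{ij}$ the
independence statistic is
$$\rho_{ij}^k = \frac{n_{ij}}{n_C} - \frac{n_i}{n_C}\frac{n_j}{n_C},$$
positive when the two genes' neighborhoods co-occur more than
independence predicts, i.e. when the genes are locally associated around
cell $k$. The box fraction 0.1 is the method's fixed constant
(`box_fraction` in `pipeline_config()`).

## Neighborhood definition and tie-breaks

Only the box *size* is fixed by the method, so the window needed a
concrete definition: we take the $m$ value-nearest cells as a contiguous
window in the per-gene (value, cell-index) sort order, clipped at the
ranking boundaries, expanding greedily and resolving equal value
distances toward the lower rank. Sorting ties on the cell index makes
counts fully deterministic, which the test suite verifies against an
independent exhaustive-scan implementation. The focal cell always
belongs to both of its own neighborhoods.

## Edge rule and its calibration

Two rules are available (`edge_rule`):

* `"z"` (default). Because both margins are fixed at $m$, the only
  random quantity under gene independence is the overlap. The focal
  cell is shared by construction, so the null overlap is
  $1 + \mathrm{Hypergeometric}(n_C-1,\, m-1,\, m-1)$ with mean
  $\mu_0 = 1 + (m-1)^2/(n_C-1)$. An edge is called when the observed
  overlap exceeds $\mu_0$ by $\Phi^{-1}(1-\alpha)$ null standard
  deviations. Centering matters: the uncentered statistic
  $\rho/\sigma$ has a positive null mean of order $9/\sqrt{n_C}$
  (about +0.4 at $n_C = 500$), which would inflate the false-edge rate
  roughly fourfold at $\alpha = 0.01$. With the centered rule the
  measured false-edge frequency on independent genes is ≈ 0.014 at
  $n_C = 500$ — the residual excess over $\alpha$ is discreteness: an
  integer count with null standard deviation ≈ 2 can only realise a
  few distinct tail sizes near 0.01, and we take the smallest integer
  threshold at or beyond the nominal quantile.
* `"literal-rho"`. Thresholds $\rho \ge \alpha$ directly — the literal
  reading of the threshold rule, retained for sensitivity analysis. It
  compares a covariance-scale quantity to a probability and is not
  calibrated as a test.

`normalized_statistic()` itself reports the plain $z = \rho/\sigma$ with
$\sigma = \sqrt{n_i n_j (n_C-n_i)(n_C-n_j) / (n_C^4 (n_C-1))}$, the
conventional normalisation; the centering lives in the edge rule where
it belongs.

Genes that are constant across all cells are excluded from edges: their
"neighborhood" is the whole population and any rule would make them
degenerate hubs. They are recorded per run (`zero_variance` on the
network set). No multiple-testing correction is applied across the
$\sim n_G^2/2$ pairs — the method specifies a fixed per-pair level, and
we follow it.

# Expression-weighted PageRank and the GIM

Each undirected edge $(i, j)$ receives the weight
$W_{ij} = E_i / \sum_{m \in L_j} E_m$, the share of gene $i$'s expression
among gene $j$'s neighbors, so incoming weights sum to one for every
connected gene. When all of a gene's neighbors have zero expression the
column falls back to uniform $1/|L_j|$ rather than dividing by zero.

The importance recursion is
$$PRW(T+1)_i = (1-d) + d \sum_{j \in L_i} PRW(T)_j\, \omega_{ji}$$
from an all-ones start, stopping at 100 iterations or when the maximum
absolute per-gene change drops below $10^{-6}$ (both configurable). Two
choices of $\omega$ ship:

* `"donor"` (default): $\omega_{ji} = W_{ij}$ — gene $j$ distributes its
  score over its neighbors in proportion to their expression, total
  outflow one. This is the standard weighted-PageRank structure and
  yields informative, non-uniform scores.
* `"literal-eq3"`: $\omega_{ji} = W_{ji}$, i.e. weights normalised over
  the receiving gene's neighborhood. Then every gene's incoming weights
  sum to one, the iteration map is an affine contraction with fixed
  point $\mathbf{1}$, and all scores converge to exactly 1 wherever
  every gene has a neighbor. The degeneracy is unit-tested; it is the
  reason the donor form is the default, since a constant score vector
  cannot rank genes.

The damping factor $d = 0.85$ is the canonical PageRank choice (the
method states none), the teleport term is $(1-d)$ per gene — not
$(1-d)/n_G$ — following the recursion as written, and isolated genes
score exactly $1-d$. For $d < 1$ the iteration contracts, and the direct
linear solve $(I - d\,\Omega)x = (1-d)\mathbf{1}$ is used as the test
oracle. Column $k$ of the GIM is the converged score vector of cell
$k$'s weighted network; convergence status and iteration counts are
stored per cell.

# Representative networks

The representative network of a cell group weights edge $i$–$j$ by the
fraction of the group's cells whose network contains it — a presence
frequency in $[0, 1]$, comparable across groups of different sizes.
Expression weights are deliberately not folded in here: the frequency
rule is the method's aggregation, and mixing scales would break the
cross-type comparability the normalisation exists for. Node degrees of
the binarised network are attached for plotting exports (TSV/GraphML);
layout and rendering are out of scope.

# Structural entropy

For a cell's network restricted to a gene subset, degrees are counted on
the induced subgraph (isolated genes contribute degree 0), the degree
probability is $p(d) = n(d)/n_G$, and
$$H = -\sum_d p(d) \log p(d), \qquad 0\log 0 \equiv 0.$$
Summing over observed degrees is mathematically identical to the full
$0 \dots n_G - 1$ range under that convention. Entropy is computed on
the *binary* adjacency — the definition operates on degrees, not
weights. Natural log is the default; the base is exposed and only
rescales. Regular graphs give $H = 0$, and $H \le \log(\text{support
size})$ always.

Group comparisons report per-group means, standard deviations, and a
two-sided Mann–Whitney U test. The method's own account compares
distributions via violin plots without naming a test; Mann–Whitney was
chosen because entropies are bounded, non-Gaussian, and group sizes are
unbalanced in real data.

# Markers and dark genes

Per-gene two-sample t-tests use Welch's unequal-variance form by default
(real age groups are heavily unbalanced; a pooled-variance Student
variant is available). Genes are ranked by raw p, ties by $|t|$ then
gene id, so rankings are deterministic; Benjamini–Hochberg adjusted
p-values are attached. Top-$k$ lists use the raw-p ranking (matching how
marker lists are conventionally drawn), while *dark genes* — significant
in the GIM, not in the GEM — are called on adjusted p at
`alpha_net = alpha_expr = 0.05`. Genes with zero variance in both groups
have no defined t statistic and are assigned $p = 1$ and logged.

# Evaluation

Cells are embedded by PCA (per-gene centering, deterministic sign: the
largest-magnitude loading of each component is made positive) and
clustered by k-means with $k = 2$ and 10 restarts under a caller-supplied
seed, on every pair of the leading principal components (1-based
indices). Partitions are scored against the true age labels by ARI, NMI
(arithmetic-mean normalisation) and the Fowlkes–Mallows index, all
implemented from the contingency table and cross-checked in the tests
against independent pair-counting oracles. All three metrics are
invariant to cluster relabeling, so the arbitrary k-means numbering is
harmless. Scoring on 2-D subspaces mirrors how such embeddings are
actually inspected; the scan reports every pair so the best subspace per
feature space is explicit rather than cherry-picked.

# The synthetic generator

`generate_gem()` draws, per age group, a latent genes × cells Gaussian
in which each co-expression block shares $\sqrt{r}$ of a common factor —
giving *exact* pairwise latent correlation $r$ within the block while
leaving every gene's marginal standard normal regardless of membership.
Latents are scaled (sd 1.0), shifted by per-gene group effects,
exponentiated around per-gene baselines drawn uniformly on
$[\log 10, \log 100]$, and observed as Poisson counts. The baseline
range and latent scale were fixed once so that realised log1p-scale
within-block correlations stay within ±0.1 of the latent target for
targets 0.5–0.9 at 500 cells; weaker expression would attenuate
correlations below that band.

Because block membership never alters a marginal, dark genes are planted
*exactly*: their distribution is identical in both groups while their
neighborhood changes. The dark preset swaps membership (half the dark
genes leave a companion block with age, half join it) so the number of
connected genes stays constant — otherwise the global PageRank score
pool shifts slightly and, at 600 cells, that artifact alone reaches
significance in unrelated genes. Planted expression markers shift half
up, half down, keeping library sizes balanced between groups for the
same reason.

Presets encode the study conditions used throughout the tests:

* `regime_presets("increase"/"flat"/"decrease")` — young vs. old block
  structure chosen so the degree distribution's diversity (and hence
  entropy) rises, stays, or falls with age; the rewired presets place
  young and old blocks on disjoint gene ranges, since ageing in this
  model rewires modules rather than resizing them in place.
* `rewired_truth()` — equal-size blocks on disjoint ranges in the two
  groups: no marginal signal at all, pure network rewiring. This is the
  scenario in which the GIM should, and in tests does, separate the
  groups while raw expression does not.
* `dark_gene_truth()` — stable blocks, a companion block with swapping
  dark members, and balanced expression markers.

What the generator does **not** emulate: dropout/zero inflation beyond
what Poisson sampling produces, negative within-block correlations,
batch effects, multiple interacting cell types (each run is one cell
type), or the scale of real atlases. Passing tests therefore demonstrate
that the statistics recover planted structure under a clean count model
at desk scale — not that the pipeline is robust to every artifact of
real scRNA-seq data.

# Problem sizes and runtime

The test suite and the acceptance script run at 100–200 genes and
300–600 cells per dataset — sized so planted structure is comfortably
identifiable while a full multi-replicate validation (30 regime runs,
10 rewiring runs with full GIMs, multi-seed calibration at 500 cells)
completes in minutes on one CPU. Per-cell network construction is
compiled (bitset intersection counts over all gene pairs); everything
downstream is plain R on sparse matrices.

# Known limitations

* The per-pair significance level is not corrected for the
  $\sim n_G^2/2$ tests, by design fidelity; per-cell networks therefore
  carry a predictable floor of false edges (≈ 1.4% at the defaults).
* Edge calibration inherits the discreteness of the overlap count: the
  realised false-edge rate can sit a few thousandths above the nominal
  level, and no deterministic integer threshold can do better.
* PageRank score conservation means importance contrasts are driven by
  connected-vs-isolated transitions and expression shares, not by block
  size per se; dense structural changes that preserve connectivity can
  be nearly invisible to mean scores.
* The Mann–Whitney comparison treats cells as independent replicates,
  as the violin-plot comparisons it formalises implicitly do.
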