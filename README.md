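# cense — cell-specific gene networks and network structural entropy

`cense` analyses single-cell RNA-seq data at the level of *per-cell gene
networks* rather than per-gene expression alone. It is aimed at questions
where groups of cells (here: young vs. old cells of a skin cell type)
differ in how genes are wired together, not only in how much they are
expressed — ageing being the motivating case: gene regulatory networks can
rewire, gain or lose complexity while marginal expression barely moves.

## The method

Starting from a preprocessed gene expression matrix (GEM, genes × cells,
library-size normalised and log1p-transformed), the pipeline computes:

1. **Cell-specific networks.** For each cell *k* and gene pair (*i*, *j*),
   two neighborhoods hold the `m = round(0.1 · n_C)` cells whose expression
   of gene *i* (resp. *j*) is nearest to cell *k*'s. With marginal counts
   *n_i*, *n_j* and overlap *n_ij*, the independence statistic is

   ρ<sub>ij</sub><sup>k</sup> = n<sub>ij</sub>/n<sub>C</sub> −
   (n<sub>i</sub>/n<sub>C</sub>)(n<sub>j</sub>/n<sub>C</sub>).

   An edge is called when the overlap exceeds its exact null expectation
   (1 + hypergeometric, since cell *k* sits in both neighborhoods) by the
   upper-tail normal quantile at significance level α = 0.01. The result
   is one sparse symmetric gene network per cell.

2. **Expression-weighted PageRank → GIM.** Each edge (*i*, *j*) carries
   the weight W<sub>ij</sub> = E<sub>i</sub> / Σ<sub>m∈L<sub>j</sub></sub>
   E<sub>m</sub> (the share of gene *i*'s expression among gene *j*'s
   neighbors). Gene importance follows the damped recursion
   PRW(T+1)<sub>i</sub> = (1 − d) + d Σ<sub>j</sub> PRW(T)<sub>j</sub>
   ω<sub>ji</sub> (d = 0.85, at most 100 iterations, tolerance 1e−6),
   with donor-normalised transition weights by default — each gene
   distributes its score over its neighbors in proportion to their
   expression. Stacking the per-cell score vectors gives the
   **gene importance matrix (GIM)**, a drop-in replacement feature space
   for the GEM.

3. **Representative networks.** Per cell type and age group, the weight
   of edge *i*–*j* is the fraction of that group's cells whose network
   contains the edge, enabling side-by-side young/old marker-gene
   networks.

4. **Network structural entropy.** For each cell's network (or a
   marker-gene subnetwork), the degree probability p(d) = n(d)/n_G feeds
   the Shannon entropy H = −Σ<sub>d</sub> p(d) log p(d): 0 for regular
   (single-degree) networks, larger for diverse degree structure. Young
   and old distributions are compared by a two-sided Mann–Whitney test.

5. **Markers, dark genes, evaluation.** Per-gene Welch t-tests rank
   markers in either feature space; **dark genes** are significant in the
   GIM but not in the GEM (Benjamini–Hochberg-adjusted p at 0.05 in both
   tests) — genes that rewire without changing expression. k-means on
   principal-component pairs, scored by ARI/NMI/Fowlkes–Mallows against
   the known age labels, quantifies how much better the GIM separates the
   groups.

A synthetic-data generator plants block-correlation structure (per-group
co-expression modules, mean shifts, dark genes, entropy regimes) through a
latent Gaussian factor model with log-normal–Poisson counts, so every
stage can be validated against known ground truth.

## Worked example

```r
library(cense)

sim <- generate_gem(200, 150, regime_presets("increase", seed = 7))
gem <- preprocess_gem(sim$gem)
cfg <- pipeline_config(seed = 7)

nets <- build_all_networks(gem, cfg)
#> CellNetworkSet: 300 cells, 200 genes, box m=30, rule=z (alpha=0.01, min n_ij=8)
#>   edges per cell: median 327 [234, 654]

gim <- build_gim(gem, nets, cfg)
#> ImportanceMatrix: 200 genes x 300 cells (variant=donor, d=0.85, 300/300 cells converged)

et  <- per_cell_entropy(nets, gem$cell_meta)
cmp <- compare_groups(et, "synthetic")
sprintf("old-minus-young mean entropy: %+.3f (Mann-Whitney p = %.2g)",
        cmp$mean_diff, cmp$p_value)
#> "old-minus-young mean entropy: +0.145 (Mann-Whitney p = 3.6e-07)"

mk <- t_test_markers(gim$values, gem$cell_meta$age_group, k = 5,
                     matrix_kind = "GIM")
head(attr(mk, "top_up_in_old"))
#> [1] "g144" "g162" "g148" "g158" "g168"
```

The simulated "increase" regime plants uniform small co-expression blocks
in young cells and diverse block sizes in old cells: per-cell networks
hold a few hundred edges each, old cells' degree distributions spread over
more values, and the recovered mean entropy difference is positive and
highly significant — matching the planted direction. The top GIM markers
are genes from the old-specific blocks (genes 101–184 in this preset),
i.e. genes whose network importance, not expression, separates the
groups.

The same pipeline runs from a YAML config (`run_pipeline("run.yaml")`) or
the command line (`inst/cli/cense run --config run.yaml`), writing all
stage outputs plus a JSON manifest into one run directory; see
`?run_pipeline` for the config layout.

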