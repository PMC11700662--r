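#' Planted ground truth for a synthetic expression matrix
#'
#' Describes the group-specific latent correlation structure a synthetic
#' GEM is generated from: disjoint co-expression blocks per age group (a
#' gene may belong to different blocks, or none, in the two groups -- that
#' is how "dark" genes are planted), per-gene additive mean shifts on the
#' latent log scale, and the ids of planted dark genes.
#'
#' Blocks are realized through a one-factor model per block (block members
#' share `sqrt(r)` of a common factor), which gives exact pairwise latent
#' correlation `r` inside the block and leaves every gene's marginal
#' distribution standard normal regardless of membership. Dark genes
#' therefore have identical marginals in both groups by construction, and
#' must have zero mean shift (enforced).
#'
#' @param n_genes Number of genes.
#' @param blocks_young,blocks_old Lists of blocks, each a
#'   `list(genes = <integer indices>, cor = <target correlation in
#'   [0, 0.99]>)`; blocks must be disjoint within a group.
#' @param mean_shift_young,mean_shift_old Numeric vectors of length
#'   `n_genes` (latent-scale additive shifts; default all zero).
#' @param dark_gene_ids Integer indices of planted dark genes (genes whose
#'   block membership differs between groups but whose marginals match).
#' @param entropy_regime One of `"increase"`, `"flat"`, `"decrease"`,
#'   `"custom"`.
#' @param seed Integer seed for [generate_gem()].
#' @param base_log_mean_range Range the per-gene baseline log mean
#'   expression is drawn from, uniform (default `log(10)` to `log(100)`;
#'   together with `latent_sd` this keeps realized log1p-scale
#'   correlations close to the latent targets).
#' @param latent_sd Scale of the latent log-normal variation (default 1).
#' @return A `SyntheticTruth` list.
#' @export
synthetic_truth <- function(n_genes, blocks_young = list(),
                            blocks_old = list(),
                            mean_shift_young = numeric(n_genes),
                            mean_shift_old = numeric(n_genes),
                            dark_gene_ids = integer(),
                            entropy_regime = "custom", seed = 1L,
                            base_log_mean_range = c(log(10), log(100)),
                            latent_sd = 1) {
  check_blocks <- function(blocks, label) {
    all_genes <- unlist(lapply(blocks, `[[`, "genes"))
    if (anyDuplicated(all_genes))
      stop("overlapping blocks in ", label)
    if (length(all_genes) && (min(all_genes) < 1 || max(all_genes) > n_genes))
      stop("block gene index out of range in ", label)
    for (b in blocks) {
      if (length(b$genes) < 2) stop("blocks need at least 2 genes")
      if (b$cor < 0 || b$cor > 0.99)
        stop("block correlation must be in [0, 0.99]; got ", b$cor,
             " (negative equicorrelation is not positive definite here)")
    }
  }
  check_blocks(blocks_young, "blocks_young")
  check_blocks(blocks_old, "blocks_old")
  stopifnot(length(mean_shift_young) == n_genes,
            length(mean_shift_old) == n_genes)
  if (length(dark_gene_ids)) {
    if (any(mean_shift_young[dark_gene_ids] != 0) ||
        any(mean_shift_old[dark_gene_ids] != 0))
      stop("dark genes must have zero mean shift in both groups")
  }
  structure(list(n_genes = as.integer(n_genes),
                 blocks = list(young = blocks_young, old = blocks_old),
                 mean_shifts = cbind(young = mean_shift_young,
                                     old = mean_shift_old),
                 dark_gene_ids = as.integer(dark_gene_ids),
                 entropy_regime = entropy_regime, seed = as.integer(seed),
                 base_log_mean_range = base_log_mean_range,
                 latent_sd = latent_sd),
            class = "SyntheticTruth")
}

#' @export
print.SyntheticTruth <- function(x, ...) {
  cat(sprintf(paste0("SyntheticTruth: %d genes, regime=%s, seed=%d, ",
                     "%d/%d blocks (young/old), %d dark genes\n"),
              x$n_genes, x$entropy_regime, x$seed,
              length(x$blocks$young), length(x$blocks$old),
              length(x$dark_gene_ids)))
  invisible(x)
}

# latent genes x cells draw for one group: factor-model blocks on top of
# iid N(0,1); every gene's marginal is exactly standard normal
.latent_group <- function(n_genes, n_cells, blocks, shift) {
  z <- matrix(rnorm(n_genes * n_cells), n_genes, n_cells)
  for (b in blocks) {
    f <- rnorm(n_cells)
    r <- b$cor
    z[b$genes, ] <- sqrt(r) * matrix(f, length(b$genes), n_cells,
                                     byrow = TRUE) +
      sqrt(1 - r) * z[b$genes, , drop = FALSE]
  }
  z + shift
}

#' Generate a synthetic expression matrix with known structure
#'
#' Draws, per group, a latent genes x cells Gaussian with the planted block
#' correlation structure, exponentiates it to log-normal Poisson rates
#' (`rate = exp(base + latent_sd * z)` with per-gene baselines shared
#' between groups), and samples counts. Cells are labeled `young`/`old`;
#' the whole draw is deterministic under `truth$seed`.
#'
#' @param n_genes Number of genes (must match `truth$n_genes`).
#' @param n_cells_per_group Cells per age group.
#' @param truth A [synthetic_truth()].
#' @param cell_type Cell type label for the metadata (default
#'   `"synthetic"`).
#' @return List with `gem` (a raw `ExpressionMatrix`, young cells first)
#'   and `truth`.
#' @export
generate_gem <- function(n_genes, n_cells_per_group, truth,
                         cell_type = "synthetic") {
  stopifnot(inherits(truth, "SyntheticTruth"),
            n_genes == truth$n_genes, n_cells_per_group >= 1)
  withr_seed(truth$seed, {
    base <- runif(n_genes, truth$base_log_mean_range[1],
                  truth$base_log_mean_range[2])
    zy <- .latent_group(n_genes, n_cells_per_group, truth$blocks$young,
                        truth$mean_shifts[, "young"])
    zo <- .latent_group(n_genes, n_cells_per_group, truth$blocks$old,
                        truth$mean_shifts[, "old"])
    lam <- exp(truth$latent_sd * cbind(zy, zo) + base)
    counts <- matrix(rpois(length(lam), lam), n_genes)
  })
  gene_ids <- sprintf("g%03d", seq_len(n_genes))
  cell_ids <- c(sprintf("young_%03d", seq_len(n_cells_per_group)),
                sprintf("old_%03d", seq_len(n_cells_per_group)))
  meta <- data.frame(cell_id = cell_ids,
                     age_group = rep(c("young", "old"),
                                     each = n_cells_per_group),
                     cell_type = cell_type, stringsAsFactors = FALSE)
  dimnames(counts) <- list(gene_ids, cell_ids)
  list(gem = expression_matrix(counts, cell_meta = meta), truth = truth)
}

# evenly spaced disjoint blocks over the first genes of the universe
.make_blocks <- function(sizes, cor, start = 1L) {
  out <- list()
  at <- start
  cor <- rep_len(cor, length(sizes))
  for (q in seq_along(sizes)) {
    out[[q]] <- list(genes = seq.int(at, at + sizes[q] - 1L),
                     cor = cor[q])
    at <- at + sizes[q]
  }
  out
}

#' Preset ground truths for the three entropy regimes
#'
#' Encodes the qualitative directions a cell type's network entropy can
#' take with age. `"flat"`: identical moderate block structure in both
#' groups, so the degree distributions (and entropies) match.
#' `"increase"`: the young group has uniform small blocks (a concentrated
#' degree distribution); the old group gains blocks of widely varying
#' sizes, including large hub-like blocks, spreading the degree
#' distribution over many values and raising its entropy. `"decrease"`:
#' the mirror image. No preset shifts any gene's mean, so the groups
#' differ in correlation structure only.
#'
#' In the `"increase"` and `"decrease"` presets the two groups' blocks
#' occupy disjoint gene ranges: aging rewires the network, it does not
#' merely re-size the young modules. This also means the gene importance
#' matrix separates the groups while per-gene expression does not -- the
#' regime presets double as the structure-only separation scenario.
#'
#' @param regime `"increase"`, `"flat"` or `"decrease"`.
#' @param n_genes Number of genes (default 200; presets need >= 185).
#' @param seed Seed stored in the truth.
#' @return A `SyntheticTruth`.
#' @export
regime_presets <- function(regime = c("increase", "flat", "decrease"),
                           n_genes = 200L, seed = 1L) {
  regime <- match.arg(regime)
  stopifnot(n_genes >= 185)
  # 84 genes each; uniform -> concentrated degrees, diverse -> spread
  uniform <- function(at) .make_blocks(rep(6L, 14L), 0.8, at)
  diverse <- function(at) .make_blocks(c(40L, 24L, 12L, 6L, 2L), 0.8, at)
  flat <- .make_blocks(c(20L, 12L, 12L, 6L, 6L, 6L), 0.8)
  pick <- switch(regime,
                 increase = list(young = uniform(1L), old = diverse(101L)),
                 flat = list(young = flat, old = flat),
                 decrease = list(young = diverse(1L), old = uniform(101L)))
  synthetic_truth(n_genes, blocks_young = pick$young,
                  blocks_old = pick$old, entropy_regime = regime,
                  seed = seed)
}

#' Preset ground truth for pure network rewiring
#'
#' Both groups carry the same number of equal-size, strongly correlated
#' blocks, but on disjoint gene ranges: aging replaces which genes are
#' co-expressed without changing any gene's marginal distribution or the
#' network's degree structure. Expression-level features therefore carry
#' no group signal at all, while gene importance changes for every block
#' gene -- the scenario in which a network-derived feature space should
#' separate the groups and raw expression should not.
#'
#' @param n_genes Number of genes (default 200; needs >= 185).
#' @param seed Seed stored in the truth.
#' @return A `SyntheticTruth`.
#' @export
rewired_truth <- function(n_genes = 200L, seed = 1L) {
  stopifnot(n_genes >= 185)
  synthetic_truth(n_genes,
                  blocks_young = .make_blocks(rep(6L, 14L), 0.9, 1L),
                  blocks_old = .make_blocks(rep(6L, 14L), 0.9, 101L),
                  entropy_regime = "flat", seed = seed)
}

#' Preset ground truth with planted dark genes
#'
#' Plants genes whose network neighborhood is rewired between groups while
#' their marginal expression distribution is unchanged. A strongly
#' correlated companion block is present in both groups; half the dark
#' genes belong to it in the young group and leave it in the old group,
#' while the other half do the reverse. Because block membership never
#' alters a gene's marginal (see [synthetic_truth()]), dark genes are
#' invisible to per-gene expression tests but change importance sharply;
#' the membership swap keeps the number of connected genes constant, so
#' the rewiring does not leak a global score-redistribution artifact into
#' unrelated genes. A set of ordinary marker genes with real mean shifts
#' is also planted (half up, half down, keeping library sizes balanced),
#' so expression-level top-k lists have genuine signal, plus stable blocks
#' shared by both groups.
#'
#' @param n_genes Number of genes (default 200; needs >= 120).
#' @param n_dark Number of dark genes (default 20, split evenly between
#'   young-members and old-members of the companion block; must be even).
#' @param n_shifted Number of ordinary differential genes (default 20,
#'   split evenly between up- and down-shifted).
#' @param shift Latent-scale mean shift magnitude of the differential
#'   genes in the old group (default 1).
#' @param seed Seed stored in the truth.
#' @return A `SyntheticTruth` with `dark_gene_ids` set.
#' @export
dark_gene_truth <- function(n_genes = 200L, n_dark = 20L, n_shifted = 20L,
                            shift = 1, seed = 1L) {
  stopifnot(n_genes >= 120, n_dark >= 2, n_dark %% 2 == 0)
  # stable blocks live on genes 1..60 in both groups
  stable <- .make_blocks(c(20L, 20L, 20L), 0.8)
  companions <- seq.int(61L, 80L)
  half_dark <- n_dark %/% 2L
  leavers <- seq.int(81L, 80L + half_dark)            # in block when young
  joiners <- seq.int(81L + half_dark, 80L + n_dark)   # in block when old
  dark <- c(leavers, joiners)
  young <- c(stable, list(list(genes = c(companions, leavers), cor = 0.9)))
  old <- c(stable, list(list(genes = c(companions, joiners), cor = 0.9)))
  shifted <- seq.int(81L + n_dark, 80L + n_dark + n_shifted)
  ms_old <- numeric(n_genes)
  half <- ceiling(n_shifted / 2)
  ms_old[shifted[seq_len(half)]] <- shift
  ms_old[shifted[-seq_len(half)]] <- -shift
  truth <- synthetic_truth(n_genes, blocks_young = young,
                           blocks_old = old, mean_shift_old = ms_old,
                           dark_gene_ids = dark,
                           entropy_regime = "custom", seed = seed)
  truth$shifted_gene_ids <- shifted
  truth
}

#' Gene ids of the planted dark genes of a truth
#' @param truth A `SyntheticTruth`.
#' @return Character gene ids (matching [generate_gem()] naming).
#' @export
dark_gene_ids <- function(truth) {
  stopifnot(inherits(truth, "SyntheticTruth"))
  sprintf("g%03d", truth$dark_gene_ids)
}

#' Write truth to JSON
#' @param truth A `SyntheticTruth`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "SyntheticTruth"))
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
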