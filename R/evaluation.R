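#' Adjusted Rand Index
#'
#' Chance-adjusted agreement between two labelings, from the contingency
#' table: `ARI = (sum_ij C(n_ij,2) - E) / (max - E)` with
#' `E = sum_i C(a_i,2) sum_j C(b_j,2) / C(n,2)`. 1 for identical
#' partitions, ~0 in expectation for independent ones.
#'
#' @param a,b Label vectors of equal length.
#' @return ARI in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  sa <- sum(choose(rowSums(tab), 2))
  sb <- sum(choose(colSums(tab), 2))
  expected <- sa * sb / choose(n, 2)
  maxi <- (sa + sb) / 2
  if (maxi == expected) return(1)            # both partitions trivial
  (sij - expected) / (maxi - expected)
}

#' Normalized Mutual Information
#'
#' Mutual information of the two labelings normalized by the arithmetic
#' mean of their entropies (natural logs; the normalization makes the base
#' irrelevant). 1 for identical partitions, 0 for independent ones; two
#' single-cluster labelings count as identical.
#'
#' @inheritParams adjusted_rand_index
#' @return NMI in `[0, 1]`.
#' @export
normalized_mutual_information <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  pij <- tab / n
  pa <- rowSums(pij)
  pb <- colSums(pij)
  ha <- -sum(pa[pa > 0] * log(pa[pa > 0]))
  hb <- -sum(pb[pb > 0] * log(pb[pb > 0]))
  if (ha == 0 && hb == 0) return(1)
  if (ha == 0 || hb == 0) return(0)
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / outer(pa, pb)[nz]))
  mi / ((ha + hb) / 2)
}

#' Fowlkes-Mallows Index
#'
#' Geometric mean of pairwise precision and recall:
#' `FMI = TP / sqrt((TP + FP)(TP + FN))` over all pairs of observations,
#' where TP counts pairs placed together in both labelings.
#'
#' @inheritParams adjusted_rand_index
#' @return FMI in `[0, 1]`.
#' @export
fowlkes_mallows_index <- function(a, b) {
  tab <- table(a, b)
  tp <- sum(choose(tab, 2))
  pa <- sum(choose(rowSums(tab), 2))
  pb <- sum(choose(colSums(tab), 2))
  if (pa == 0 || pb == 0) return(0)
  tp / sqrt(pa * pb)
}

#' PCA embedding of cells
#'
#' Centers each gene across cells and projects cells onto the top principal
#' axes. The sign of each component is fixed deterministically: the loading
#' with the largest magnitude is made positive.
#'
#' @param matrix Numeric genes x cells matrix (GEM or GIM values).
#' @param n_pcs Number of components (`<= min(n_genes, n_cells)`).
#' @return Cells x `n_pcs` coordinate matrix, with the proportion of
#'   variance explained in `attr(, "variance_explained")`.
#' @export
pca_embed <- function(matrix, n_pcs = 6L) {
  matrix <- as.matrix(matrix)
  if (n_pcs > min(dim(matrix)))
    stop("n_pcs exceeds min(n_genes, n_cells)")
  vars <- apply(matrix, 1L, var)
  if (all(vars == 0)) stop("constant matrix has no principal axes")
  pc <- prcomp(t(matrix), center = TRUE, scale. = FALSE)
  n_pcs <- min(n_pcs, ncol(pc$x))
  rot <- pc$rotation[, seq_len(n_pcs), drop = FALSE]
  flip <- vapply(seq_len(n_pcs), function(q) {
    l <- rot[, q]
    sign(l[which.max(abs(l))])
  }, 1)
  scores <- pc$x[, seq_len(n_pcs), drop = FALSE] %*% diag(flip, n_pcs)
  colnames(scores) <- paste0("PC", seq_len(n_pcs))
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  attr(scores, "variance_explained") <- ve[seq_len(n_pcs)]
  scores
}

#' Cluster a PC pair and score against the true age labels
#'
#' Runs k-means with k = 2 (10 restarts, seeded) on two selected principal
#' coordinates and scores the resulting partition against the known
#' young/old labels with ARI, NMI and FMI. All three metrics are invariant
#' to the arbitrary k-means cluster numbering.
#'
#' @param embedding Cells x PCs matrix from [pca_embed()].
#' @param pc_pair Two distinct 1-based PC indices.
#' @param true_labels Character vector (`"young"`/`"old"`) per cell.
#' @param seed Integer seed for the k-means restarts.
#' @param matrix_kind Label stored on the result.
#' @return A one-row data frame (`matrix_kind`, `pc_a`, `pc_b`, `ari`,
#'   `nmi`, `fmi`, `clustering_seed`).
#' @export
cluster_and_score <- function(embedding, pc_pair, true_labels, seed = 1L,
                              matrix_kind = "GEM") {
  embedding <- as.matrix(embedding)
  pc_pair <- as.integer(pc_pair)
  if (length(pc_pair) != 2L || pc_pair[1] == pc_pair[2])
    stop("pc_pair must be two distinct PC indices")
  if (any(pc_pair < 1 | pc_pair > ncol(embedding)))
    stop("pc_pair out of range")
  if (nrow(embedding) < 2) stop("fewer cells than clusters")
  if (length(true_labels) != nrow(embedding))
    stop("true_labels must have one entry per cell")
  xy <- embedding[, pc_pair, drop = FALSE]
  km <- withr_seed(seed, kmeans(xy, centers = 2L, nstart = 10L))
  data.frame(matrix_kind = matrix_kind, pc_a = pc_pair[1],
             pc_b = pc_pair[2],
             ari = adjusted_rand_index(km$cluster, true_labels),
             nmi = normalized_mutual_information(km$cluster, true_labels),
             fmi = fowlkes_mallows_index(km$cluster, true_labels),
             clustering_seed = as.integer(seed),
             stringsAsFactors = FALSE)
}

# evaluate expr under a local RNG state so callers' streams are untouched
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Scan all PC pairs for GEM and GIM separation
#'
#' Evaluates [cluster_and_score()] on every unordered pair of the top
#' `max_pc` principal components for both feature spaces, and reports the
#' best pair per space by ARI.
#'
#' @param gem_embedding,gim_embedding Cells x PCs matrices from
#'   [pca_embed()] of the GEM and the GIM.
#' @param true_labels Character vector (`"young"`/`"old"`) per cell.
#' @param max_pc Scan PCs 1..`max_pc` (default 6; must be >= 2).
#' @param seed Integer seed for the clustering.
#' @return Data frame with one row per (pair, matrix kind), ordered by
#'   matrix kind then pair; best rows marked in the logical column `best`
#'   (highest ARI per matrix kind, ties to the earlier pair).
#' @export
pc_pair_scan <- function(gem_embedding, gim_embedding, true_labels,
                         max_pc = 6L, seed = 1L) {
  if (max_pc < 2) stop("max_pc must be at least 2")
  spaces <- list(GEM = gem_embedding, GIM = gim_embedding)
  rows <- list()
  for (kind in names(spaces)) {
    emb <- spaces[[kind]]
    mp <- min(max_pc, ncol(emb))
    for (a in seq_len(mp - 1L)) for (b in seq((a + 1L), mp))
      rows[[length(rows) + 1L]] <-
        cluster_and_score(emb, c(a, b), true_labels, seed, kind)
  }
  out <- do.call(rbind, rows)
  out$best <- FALSE
  for (kind in names(spaces)) {
    sel <- which(out$matrix_kind == kind)
    out$best[sel[which.max(out$ari[sel])]] <- TRUE
  }
  out
}
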