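#' Expression-derived edge weights for one cell
#'
#' Each undirected edge i-j of the cell's network receives two directed
#' weights: `W[i, j] = E_i / sum(E_m, m in L_j)`, where `L_j` is the set of
#' genes adjacent to `j` in that cell. Column `j` of the weight matrix thus
#' distributes mass over `j`'s neighbors in proportion to their expression
#' and sums to 1 whenever some neighbor of `j` is expressed; when all of
#' `j`'s neighbors have zero expression, the column falls back to the
#' uniform `1 / |L_j|`.
#'
#' @param gem The preprocessed `ExpressionMatrix` the network was built
#'   from.
#' @param net A `CellNetwork` for one of its cells.
#' @return A `WeightedCellNetwork`: the cell id, sparse weight matrix `W`
#'   (genes x genes, `W[i, j]` defined on edges), and the adjacency.
#' @export
#' @examples
#' # gene j with neighbors i and m, E_i = 2, E_m = 6 -> W_ij = 0.25,
#' # W_mj = 0.75
edge_weights <- function(gem, net) {
  stopifnot(inherits(gem, "ExpressionMatrix"), inherits(net, "CellNetwork"))
  if (!identical(net$gene_ids, gem$gene_ids))
    stop("network and GEM gene universes differ")
  k <- match(net$cell_id, gem$cell_ids)
  if (is.na(k)) stop("network cell not found in GEM")
  e <- gem$values[, k]
  adj <- as_adjacency(net)
  w <- adj * e                       # entry (i, j) = E_i on edges
  colsum <- Matrix::colSums(w)
  deg <- Matrix::colSums(adj)
  # zero-expression neighborhoods: uniform over |L_j|
  fallback <- which(colsum == 0 & deg > 0)
  if (length(fallback))
    w[, fallback] <- adj[, fallback, drop = FALSE] %*%
      Matrix::Diagonal(length(fallback), 1 / deg[fallback])
  scale <- ifelse(colsum > 0, 1 / colsum, 1)
  w <- w %*% Matrix::Diagonal(length(scale), scale)
  dimnames(w) <- dimnames(adj)
  structure(list(cell_id = net$cell_id, W = w, adjacency = adj,
                 expression = e, gene_ids = net$gene_ids),
            class = "WeightedCellNetwork")
}

#' @export
print.WeightedCellNetwork <- function(x, ...) {
  cat(sprintf("WeightedCellNetwork %s: %d genes, %d directed weights\n",
              x$cell_id, length(x$gene_ids), Matrix::nnzero(x$W)))
  invisible(x)
}

#' Weighted PageRank of one cell network
#'
#' Iterates `PRW(T+1)_i = (1 - d) + d * sum_j PRW(T)_j * omega_ji` from the
#' all-ones start until the maximum absolute per-gene change falls below
#' `cfg$tol` or `cfg$max_iter` iterations are reached. Isolated genes score
#' `1 - d`.
#'
#' Two transition-weight variants are provided. `"donor"` (default): the
#' contribution of neighbor `j` to gene `i` is `W[i, j]`, i.e. every gene
#' distributes its score over its neighbors in proportion to their
#' expression (total outflow 1) -- the standard weighted-PageRank structure,
#' which yields informative, non-uniform scores. `"literal-eq3"`: the
#' contribution is `W[j, i]`, so each gene's *incoming* weights sum to 1;
#' the all-ones vector is then the unique fixed point and every gene gets
#' the same score -- this degenerate behavior is unit-tested and is why the
#' donor-normalized variant is the default.
#'
#' @param wnet A `WeightedCellNetwork` from [edge_weights()].
#' @param cfg A [pipeline_config()]; uses `damping`, `max_iter`, `tol`.
#' @param variant `"donor"` or `"literal-eq3"` (default from `cfg`).
#' @return List with `scores` (named, length n_genes), `iterations`,
#'   `converged`.
#' @export
weighted_pagerank <- function(wnet, cfg = pipeline_config(),
                              variant = cfg$pagerank_variant) {
  stopifnot(inherits(wnet, "WeightedCellNetwork"))
  variant <- match.arg(variant, c("donor", "literal-eq3"))
  d <- cfg$damping
  if (d <= 0 || d >= 1) stop("damping must be in (0, 1)")
  M <- if (variant == "donor") wnet$W else Matrix::t(wnet$W)
  n <- length(wnet$gene_ids)
  x <- rep(1, n)
  iterations <- cfg$max_iter
  converged <- FALSE
  for (t in seq_len(cfg$max_iter)) {
    x_new <- (1 - d) + d * as.vector(M %*% x)
    delta <- max(abs(x_new - x))
    x <- x_new
    if (delta < cfg$tol) {
      iterations <- t
      converged <- TRUE
      break
    }
  }
  names(x) <- wnet$gene_ids
  list(scores = x, iterations = iterations, converged = converged)
}

#' Assemble the gene importance matrix (GIM)
#'
#' Column `k` of the GIM is the weighted PageRank score vector of cell `k`'s
#' expression-weighted network, so the GIM has the same genes x cells shape
#' as the GEM and can replace it as a feature space.
#'
#' @param gem The preprocessed `ExpressionMatrix`.
#' @param networks The matching `CellNetworkSet` (one network per cell, in
#'   `gem` cell order).
#' @param cfg A [pipeline_config()].
#' @return An `ImportanceMatrix`: `values` (genes x cells),
#'   `iterations_used`, `converged` (per cell), `variant`, `damping`.
#' @export
build_gim <- function(gem, networks, cfg = pipeline_config()) {
  stopifnot(inherits(gem, "ExpressionMatrix"),
            inherits(networks, "CellNetworkSet"))
  if (!identical(networks$cell_ids, gem$cell_ids))
    stop("networks must cover exactly the GEM's cells, in order")
  n_C <- length(gem$cell_ids)
  vals <- matrix(0, length(gem$gene_ids), n_C,
                 dimnames = list(gem$gene_ids, gem$cell_ids))
  iters <- integer(n_C)
  conv <- logical(n_C)
  for (k in seq_len(n_C)) {
    wnet <- edge_weights(gem, networks$networks[[k]])
    pr <- weighted_pagerank(wnet, cfg)
    vals[, k] <- pr$scores
    iters[k] <- pr$iterations
    conv[k] <- pr$converged
  }
  structure(list(values = vals, iterations_used = iters, converged = conv,
                 variant = cfg$pagerank_variant, damping = cfg$damping,
                 tol = cfg$tol),
            class = "ImportanceMatrix")
}

#' @export
print.ImportanceMatrix <- function(x, ...) {
  cat(sprintf(paste0("ImportanceMatrix: %d genes x %d cells ",
                     "(variant=%s, d=%g, %d/%d cells converged)\n"),
              nrow(x$values), ncol(x$values), x$variant, x$damping,
              sum(x$converged), length(x$converged)))
  invisible(x)
}

#' Write a GIM as a genes x cells TSV
#' @param gim An `ImportanceMatrix`.
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_gim <- function(gim, path) {
  stopifnot(inherits(gim, "ImportanceMatrix"))
  df <- data.frame(gene_id = rownames(gim$values), gim$values,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
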