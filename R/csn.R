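#' Neighborhood box size
#'
#' Number of cells in each gene's expression neighborhood,
#' `round(box_fraction * n_C)` with half-up rounding, at least 1.
#'
#' @param n_C Number of cells.
#' @param box_fraction Box fraction (default 0.1).
#' @return Integer box size `m`.
#' @export
box_size <- function(n_C, box_fraction = 0.1) {
  stopifnot(n_C >= 1, box_fraction > 0, box_fraction < 1)
  m <- as.integer(floor(box_fraction * n_C + 0.5))
  if (m < 1)
    stop("box_fraction * n_C must be at least 1")
  m
}

#' Neighborhood overlap counts for one gene pair in one cell
#'
#' For cell `k` and genes `i` and `j`, each gene's neighborhood is the
#' `m = round(box_fraction * n_C)` cells whose expression values are nearest
#' to the focal cell's value (the focal cell included), taken as a contiguous
#' window in the per-gene (value, cell-index) ranking; value-distance ties
#' take the lower-rank side, so counts are deterministic. `n_ij` is the size
#' of the intersection of the two neighborhoods.
#'
#' @param gem A preprocessed `ExpressionMatrix`.
#' @param k Cell index (1-based).
#' @param i,j Gene indices (1-based).
#' @param box_fraction Box fraction (default 0.1).
#' @return List with `n_i`, `n_j`, `n_ij`, `n_C`, and the member cell
#'   indices `cells_i`, `cells_j`.
#' @export
neighborhood_counts <- function(gem, k, i, j, box_fraction = 0.1) {
  stopifnot(inherits(gem, "ExpressionMatrix"))
  if (!gem$preprocessed) stop("gem must be preprocessed")
  n_C <- length(gem$cell_ids)
  n_G <- length(gem$gene_ids)
  if (k < 1 || k > n_C) stop("cell index out of range")
  if (i < 1 || i > n_G || j < 1 || j > n_G) stop("gene index out of range")
  m <- box_size(n_C, box_fraction)
  ci <- .csn_neighborhood(gem$values[i, ], as.integer(k), m)
  cj <- .csn_neighborhood(gem$values[j, ], as.integer(k), m)
  list(n_i = length(ci), n_j = length(cj),
       n_ij = length(intersect(ci, cj)), n_C = n_C,
       cells_i = ci, cells_j = cj)
}

#' Independence statistic rho for a gene pair in a cell
#'
#' `rho = n_ij/n_C - (n_i/n_C) * (n_j/n_C)`: the deviation of the joint
#' neighborhood occupancy from the product of the marginals. Positive values
#' indicate association between the two genes in that cell.
#'
#' @param n_ij Overlap count.
#' @param n_i,n_j Marginal neighborhood counts.
#' @param n_C Total number of cells (> 0).
#' @return The statistic rho, in `[-1, 1]`.
#' @export
#' @examples
#' rho_statistic(5, 10, 10, 100)  # 0.04
rho_statistic <- function(n_ij, n_i, n_j, n_C) {
  if (any(n_C <= 0)) stop("n_C must be positive")
  if (any(n_ij < 0 | n_ij > pmin(n_i, n_j) | pmax(n_i, n_j) > n_C))
    stop("invalid neighborhood counts")
  n_ij / n_C - (n_i / n_C) * (n_j / n_C)
}

#' Normalized independence statistic
#'
#' `z = rho / sigma` with `sigma = sqrt(n_i n_j (n_C - n_i)(n_C - n_j) /
#' (n_C^4 (n_C - 1)))`, the standard deviation of rho under independence
#' with fixed margins. Undefined when a margin is 0 or `n_C`.
#'
#' @param rho Value from [rho_statistic()].
#' @inheritParams rho_statistic
#' @return The normalized statistic z.
#' @export
normalized_statistic <- function(rho, n_i, n_j, n_C) {
  if (any(n_i <= 0 | n_i >= n_C | n_j <= 0 | n_j >= n_C))
    stop("undefined variance: margins must be strictly between 0 and n_C")
  sigma <- sqrt(n_i * n_j * (n_C - n_i) * (n_C - n_j) /
                  (n_C^4 * (n_C - 1)))
  rho / sigma
}

#' Edge-calling threshold on the overlap count
#'
#' Because both margins are fixed at the box size `m`, every edge rule
#' reduces to a minimum overlap count `n_ij`.
#'
#' For `rule = "z"` the overlap is tested against its exact null
#' distribution under gene independence. The focal cell belongs to both
#' neighborhoods by construction, so the null overlap is
#' `1 + Hypergeometric(n_C - 1, m - 1, m - 1)`, with mean
#' `mu0 = 1 + (m-1)^2/(n_C-1)`; an edge is called when the overlap exceeds
#' `mu0` by `qnorm(1 - alpha)` null standard deviations (upper tail). This
#' centering keeps the false-edge rate at approximately `alpha`; thresholding
#' the uncentered statistic would be systematically liberal because the
#' shared focal cell inflates rho's null mean by `O(1/sqrt(n_C))`.
#'
#' For `rule = "literal-rho"` the statistic rho itself is compared to
#' `alpha` (`rho >= alpha` calls an edge), the threshold rule read
#' literally; it is retained for sensitivity analysis and is not
#' calibrated as a test.
#'
#' @param n_C Number of cells.
#' @param m Box size.
#' @param alpha Significance level (or literal rho threshold).
#' @param rule `"z"` or `"literal-rho"`.
#' @return Minimum integer overlap count that calls an edge (`Inf` when the
#'   null is degenerate, i.e. `m < 2` or `m >= n_C` under `"z"`).
#' @export
edge_count_threshold <- function(n_C, m, alpha = 0.01,
                                 rule = c("z", "literal-rho")) {
  rule <- match.arg(rule)
  if (rule == "literal-rho") {
    t <- n_C * alpha + m^2 / n_C
    return(ceiling(t - 1e-9))
  }
  if (m < 2 || m >= n_C || n_C < 3) return(Inf)
  mu0 <- 1 + (m - 1)^2 / (n_C - 1)
  var0 <- (m - 1)^2 * (n_C - m)^2 / ((n_C - 1)^2 * (n_C - 2))
  ceiling(mu0 + qnorm(1 - alpha) * sqrt(var0) - 1e-9)
}

# constant genes take part in no edge: their neighborhood is degenerate
# (any window rule would make them hubs of the whole population)
.zero_variance_genes <- function(values) {
  mins <- apply(values, 1L, min)
  maxs <- apply(values, 1L, max)
  maxs - mins == 0
}

.edges_to_network <- function(em, gem, k, m) {
  n_C <- length(gem$cell_ids)
  edges <- data.frame(
    gene_i = gem$gene_ids[em[, 1]], gene_j = gem$gene_ids[em[, 2]],
    n_ij = em[, 3],
    stringsAsFactors = FALSE
  )
  rho <- rho_statistic(em[, 3], m, m, n_C)
  edges$z <- if (nrow(em) && m > 0 && m < n_C)
    normalized_statistic(rho, m, m, n_C) else numeric(nrow(em))
  structure(list(cell_id = gem$cell_ids[k], edges = edges,
                 i = em[, 1], j = em[, 2],
                 n_genes = length(gem$gene_ids),
                 gene_ids = gem$gene_ids, m = m, n_C = n_C),
            class = "CellNetwork")
}

#' Build the gene correlation network of one cell
#'
#' For every unordered gene pair, an edge is present iff the pair passes the
#' configured edge rule (see [edge_count_threshold()]) at level `cfg$alpha`.
#' The result is a symmetric, zero-diagonal binary network over all genes;
#' constant genes take part in no edge.
#'
#' @param gem A preprocessed `ExpressionMatrix`.
#' @param k Cell index (1-based).
#' @param cfg A [pipeline_config()].
#' @return A `CellNetwork`: cell id, edge data frame (`gene_i`, `gene_j`,
#'   `n_ij`, `z`), and the gene universe.
#' @export
build_cell_network <- function(gem, k, cfg = pipeline_config()) {
  build_all_networks(gem, cfg, cells = k)$networks[[1L]]
}

#' Build one gene correlation network per cell
#'
#' Applies the per-cell construction to every cell (or a subset); output
#' order matches `gem$cell_ids`. Cells are processed independently, so
#' results do not depend on processing order.
#'
#' @inheritParams build_cell_network
#' @param cells Optional integer vector of cell indices (default all).
#' @return A `CellNetworkSet`: list of `CellNetwork`s plus shared metadata.
#' @export
build_all_networks <- function(gem, cfg = pipeline_config(), cells = NULL) {
  stopifnot(inherits(gem, "ExpressionMatrix"))
  if (!gem$preprocessed) stop("gem must be preprocessed")
  n_C <- length(gem$cell_ids)
  if (is.null(cells)) cells <- seq_len(n_C)
  cells <- as.integer(cells)
  if (any(cells < 1 | cells > n_C)) stop("cell index out of range")
  m <- box_size(n_C, cfg$box_fraction)
  thr <- edge_count_threshold(n_C, m, cfg$alpha, cfg$edge_rule)
  skip <- .zero_variance_genes(gem$values)
  ems <- .csn_edges(gem$values, cells, m,
                    if (is.finite(thr)) thr else n_C + 1, skip)
  nets <- lapply(seq_along(cells), function(idx)
    .edges_to_network(ems[[idx]], gem, cells[idx], m))
  structure(list(networks = nets, cell_ids = gem$cell_ids[cells],
                 gene_ids = gem$gene_ids, m = m, n_C = n_C,
                 edge_rule = cfg$edge_rule, alpha = cfg$alpha,
                 box_fraction = cfg$box_fraction, min_n_ij = thr,
                 zero_variance = gem$gene_ids[skip]),
            class = "CellNetworkSet")
}

#' @export
print.CellNetworkSet <- function(x, ...) {
  ne <- vapply(x$networks, function(n) nrow(n$edges), 1L)
  cat(sprintf(paste0("CellNetworkSet: %d cells, %d genes, box m=%d, ",
                     "rule=%s (alpha=%g, min n_ij=%s)\n"),
              length(x$networks), length(x$gene_ids), x$m, x$edge_rule,
              x$alpha, format(x$min_n_ij)))
  cat(sprintf("  edges per cell: median %s [%s, %s]\n",
              stats::median(ne), min(ne), max(ne)))
  if (length(x$zero_variance))
    cat("  constant genes excluded:", length(x$zero_variance), "\n")
  invisible(x)
}

#' @export
print.CellNetwork <- function(x, ...) {
  cat(sprintf("CellNetwork %s: %d genes, %d edges\n", x$cell_id,
              x$n_genes, nrow(x$edges)))
  invisible(x)
}

#' Sparse symmetric adjacency of a cell network
#'
#' @param net A `CellNetwork`.
#' @return A symmetric 0/1 `Matrix::sparseMatrix` with zero diagonal,
#'   dimnames set to the gene universe.
#' @export
as_adjacency <- function(net) {
  stopifnot(inherits(net, "CellNetwork"))
  n <- net$n_genes
  Matrix::sparseMatrix(i = c(net$i, net$j), j = c(net$j, net$i), x = 1,
                       dims = c(n, n),
                       dimnames = list(net$gene_ids, net$gene_ids))
}

#' Number of edges in a cell network
#' @param net A `CellNetwork`.
#' @return Integer edge count.
#' @export
n_edges <- function(net) nrow(net$edges)

#' Write / read a per-cell edge-list store
#'
#' One TSV row per (cell, edge): `cell_id`, `gene_i`, `gene_j`, `n_ij`, `z`.
#' Round-trips through [read_networks()] given the gene and cell universes.
#'
#' @param nets A `CellNetworkSet`.
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_networks <- function(nets, path) {
  stopifnot(inherits(nets, "CellNetworkSet"))
  tabs <- lapply(nets$networks, function(n)
    if (nrow(n$edges)) cbind(cell_id = n$cell_id, n$edges) else NULL)
  tab <- do.call(rbind, tabs)
  if (is.null(tab))
    tab <- data.frame(cell_id = character(), gene_i = character(),
                      gene_j = character(), n_ij = integer(),
                      z = numeric())
  write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_networks
#' @param path Edge-list TSV written by [write_networks()].
#' @param gene_ids,cell_ids Gene and cell universes of the original set.
#' @param m,n_C Box size and cell count recorded for the statistics.
#' @return For `read_networks`, a `CellNetworkSet`.
#' @export
read_networks <- function(path, gene_ids, cell_ids, m, n_C) {
  tab <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(cell_id = "character",
                                   gene_i = "character",
                                   gene_j = "character"))
  nets <- lapply(cell_ids, function(cid) {
    sub <- tab[tab$cell_id == cid, , drop = FALSE]
    i <- match(sub$gene_i, gene_ids)
    j <- match(sub$gene_j, gene_ids)
    if (anyNA(i) || anyNA(j)) stop("edge gene not in gene universe")
    structure(list(cell_id = cid,
                   edges = data.frame(gene_i = sub$gene_i,
                                      gene_j = sub$gene_j,
                                      n_ij = sub$n_ij, z = sub$z,
                                      stringsAsFactors = FALSE),
                   i = i, j = j, n_genes = length(gene_ids),
                   gene_ids = gene_ids, m = m, n_C = n_C),
              class = "CellNetwork")
  })
  structure(list(networks = nets, cell_ids = cell_ids, gene_ids = gene_ids,
                 m = m, n_C = n_C, edge_rule = NA_character_, alpha = NA,
                 box_fraction = NA, min_n_ij = NA,
                 zero_variance = character()),
            class = "CellNetworkSet")
}
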