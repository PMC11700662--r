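#' Representative (cell-type) network
#'
#' Aggregates per-cell binary networks into one network for a group of
#' cells: the weight of edge i-j is the fraction of the group's cells whose
#' network contains that edge (number of cells with the correlated pair
#' divided by the number of cells), restricted to a gene subset. Weights are
#' therefore comparable across groups and lie in `[0, 1]`.
#'
#' @param networks A `CellNetworkSet`.
#' @param cells Character vector of cell ids to aggregate (non-empty subset
#'   of the set's cells).
#' @param gene_subset Gene ids to restrict to (default: all genes).
#' @param cell_type,age_group Labels stored on the result (`age_group`
#'   conventionally `"young"`, `"old"` or `"combined"`).
#' @return A `TypeNetwork`: `edge_freq` (symmetric matrix over
#'   `gene_subset`), `n_cells`, `degree` (node degree of the binarized
#'   restricted network, for plotting exports), and the labels.
#' @export
representative_network <- function(networks, cells = networks$cell_ids,
                                   gene_subset = networks$gene_ids,
                                   cell_type = "all",
                                   age_group = "combined") {
  stopifnot(inherits(networks, "CellNetworkSet"))
  cells <- as.character(cells)
  if (!length(cells)) stop("empty cell subset")
  idx <- match(cells, networks$cell_ids)
  if (anyNA(idx)) stop("unknown cell id(s): ",
                       paste(cells[is.na(idx)][1:min(3, sum(is.na(idx)))],
                             collapse = ", "))
  gi <- match(gene_subset, networks$gene_ids)
  if (anyNA(gi)) stop("gene_subset contains genes outside the universe")
  ns <- length(gene_subset)
  counts <- matrix(0, ns, ns, dimnames = list(gene_subset, gene_subset))
  remap <- rep(NA_integer_, length(networks$gene_ids))
  remap[gi] <- seq_len(ns)
  for (q in idx) {
    net <- networks$networks[[q]]
    ri <- remap[net$i]
    rj <- remap[net$j]
    keep <- !is.na(ri) & !is.na(rj)
    if (any(keep)) {
      ii <- ri[keep]; jj <- rj[keep]
      counts[cbind(ii, jj)] <- counts[cbind(ii, jj)] + 1
      counts[cbind(jj, ii)] <- counts[cbind(jj, ii)] + 1
    }
  }
  freq <- counts / length(idx)
  structure(list(cell_type = cell_type, age_group = age_group,
                 gene_subset = gene_subset, edge_freq = freq,
                 n_cells = length(idx),
                 degree = rowSums(freq > 0)),
            class = "TypeNetwork")
}

#' @export
print.TypeNetwork <- function(x, ...) {
  cat(sprintf(paste0("TypeNetwork (%s / %s): %d genes, %d cells, ",
                     "%d edges with nonzero frequency\n"),
              x$cell_type, x$age_group, length(x$gene_subset), x$n_cells,
              sum(x$edge_freq[upper.tri(x$edge_freq)] > 0)))
  invisible(x)
}

.restrict_type_network <- function(net, genes) {
  gi <- match(genes, net$gene_subset)
  if (anyNA(gi)) stop("genes outside the network's gene set")
  freq <- net$edge_freq[gi, gi, drop = FALSE]
  structure(list(cell_type = net$cell_type, age_group = net$age_group,
                 gene_subset = genes, edge_freq = freq,
                 n_cells = net$n_cells, degree = rowSums(freq > 0)),
            class = "TypeNetwork")
}

#' Mixed marker network: young and old networks on a shared gene set
#'
#' Re-expresses a young and an old representative network of the same cell
#' type on the union of the two groups' marker lists (aligned gene
#' ordering), ready for side-by-side comparison of how marker-gene
#' interactions change with age.
#'
#' @param young_net,old_net `TypeNetwork`s sharing a `cell_type`.
#' @param young_markers,old_markers Character vectors of marker gene ids.
#' @return A `MixedMarkerNetwork`: list with `young` and `old`
#'   `TypeNetwork`s on the aligned union gene set, and `genes`.
#' @export
mixed_marker_network <- function(young_net, old_net, young_markers,
                                 old_markers) {
  stopifnot(inherits(young_net, "TypeNetwork"),
            inherits(old_net, "TypeNetwork"))
  if (!identical(young_net$cell_type, old_net$cell_type))
    stop("networks belong to different cell types")
  if (!length(intersect(young_net$gene_subset, old_net$gene_subset)))
    stop("disjoint gene universes")
  genes <- union(young_markers, old_markers)
  structure(list(young = .restrict_type_network(young_net, genes),
                 old = .restrict_type_network(old_net, genes),
                 genes = genes, cell_type = young_net$cell_type),
            class = "MixedMarkerNetwork")
}

#' Export a representative network
#'
#' Writes an edge-list TSV (`gene_i`, `gene_j`, `frequency`, `group`; zero
#' frequencies omitted) and, optionally, GraphML for external viewers, with
#' node degree stored as a vertex attribute.
#'
#' @param net A `TypeNetwork`.
#' @param path Output TSV path.
#' @param graphml Optional GraphML output path.
#' @return `path`, invisibly.
#' @export
write_type_network <- function(net, path, graphml = NULL) {
  stopifnot(inherits(net, "TypeNetwork"))
  ut <- which(upper.tri(net$edge_freq) & net$edge_freq > 0, arr.ind = TRUE)
  tab <- data.frame(gene_i = net$gene_subset[ut[, 1]],
                    gene_j = net$gene_subset[ut[, 2]],
                    frequency = net$edge_freq[ut],
                    group = net$age_group)
  write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(graphml)) {
    g <- igraph::graph_from_adjacency_matrix(net$edge_freq, mode = "undirected",
                                             weighted = TRUE, diag = FALSE)
    igraph::V(g)$degree <- net$degree
    igraph::write_graph(g, graphml, format = "graphml")
  }
  invisible(path)
}
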