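#' Degree distribution of a cell network on a gene subset
#'
#' Degrees are computed on the subnetwork induced by `gene_subset` (genes in
#' the subset, edges with both endpoints inside it); genes with no edges
#' contribute degree 0. The degree probability is `p(d) = n(d) / n_genes`,
#' where `n(d)` counts the subset genes of degree `d`.
#'
#' @param net A `CellNetwork`.
#' @param gene_subset Non-empty character vector of gene ids (default: the
#'   whole gene universe).
#' @return A `DegreeDistribution`: `degrees` (observed degree values),
#'   `counts`, `probs`, `n_genes`, and the raw per-gene `degree_sequence`.
#' @export
#' @examples
#' # 3-node path a-b, b-c: p(1) = 2/3, p(2) = 1/3
degree_distribution <- function(net, gene_subset = net$gene_ids) {
  stopifnot(inherits(net, "CellNetwork"))
  if (!length(gene_subset)) stop("gene_subset must be non-empty")
  gi <- match(gene_subset, net$gene_ids)
  if (anyNA(gi)) stop("unknown gene id(s) in gene_subset")
  remap <- rep(NA_integer_, net$n_genes)
  remap[gi] <- seq_along(gi)
  ri <- remap[net$i]
  rj <- remap[net$j]
  keep <- !is.na(ri) & !is.na(rj)
  degs <- tabulate(c(ri[keep], rj[keep]), nbins = length(gi))
  tab <- table(degs)
  d <- as.integer(names(tab))
  counts <- as.integer(tab)
  structure(list(degrees = d, counts = counts,
                 probs = counts / length(gi), n_genes = length(gi),
                 degree_sequence = stats::setNames(degs, gene_subset)),
            class = "DegreeDistribution")
}

#' Network structural entropy
#'
#' Shannon entropy of the degree probability distribution,
#' `H = -sum_d p(d) log p(d)` with the convention `0 log 0 = 0`. A regular
#' graph (single degree value) has entropy 0; the maximum over a support of
#' `m` distinct degrees is `log m`. Natural log by default; the base only
#' rescales.
#'
#' @param dd A `DegreeDistribution` from [degree_distribution()].
#' @param log_base Logarithm base (default natural).
#' @return The entropy, a non-negative scalar.
#' @export
structural_entropy <- function(dd, log_base = exp(1)) {
  stopifnot(inherits(dd, "DegreeDistribution"), log_base > 0, log_base != 1)
  p <- dd$probs[dd$probs > 0]
  -sum(p * log(p)) / log(log_base)
}

#' Per-cell structural entropy over labeled gene subsets
#'
#' Computes one entropy per cell per gene subset (an `"all-genes"` subset is
#' always appended), carrying each cell's type and age-group labels, plus a
#' per-(cell_type, age_group, subset) summary of mean, sd and n.
#'
#' @param networks A `CellNetworkSet`.
#' @param cell_meta Data frame with `cell_id`, `age_group`, `cell_type`
#'   covering the set's cells (e.g. `gem$cell_meta`).
#' @param marker_sets Named list of gene-id vectors; names must be unique
#'   and are used as subset labels.
#' @param log_base Logarithm base for the entropy.
#' @return An `EntropyTable`: data frame (`cell_id`, `cell_type`,
#'   `age_group`, `subset`, `entropy`) with the summary data frame in
#'   `attr(, "summary")`.
#' @export
per_cell_entropy <- function(networks, cell_meta, marker_sets = list(),
                             log_base = exp(1)) {
  stopifnot(inherits(networks, "CellNetworkSet"))
  if (anyDuplicated(names(marker_sets)))
    stop("marker_sets labels must be unique")
  if ("all-genes" %in% names(marker_sets))
    stop('"all-genes" is a reserved subset label')
  sets <- c(marker_sets, list(`all-genes` = networks$gene_ids))
  meta <- as.data.frame(cell_meta)
  mi <- match(networks$cell_ids, meta$cell_id)
  if (anyNA(mi)) stop("cell_meta does not cover every network cell")
  rows <- vector("list", length(networks$networks) * length(sets))
  r <- 0L
  for (k in seq_along(networks$networks)) {
    net <- networks$networks[[k]]
    for (s in names(sets)) {
      r <- r + 1L
      h <- structural_entropy(degree_distribution(net, sets[[s]]),
                              log_base)
      rows[[r]] <- data.frame(cell_id = net$cell_id,
                              cell_type = meta$cell_type[mi[k]],
                              age_group = meta$age_group[mi[k]],
                              subset = s, entropy = h,
                              stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  agg_mean <- stats::aggregate(entropy ~ cell_type + age_group + subset,
                               tab, mean)
  agg_sd <- stats::aggregate(entropy ~ cell_type + age_group + subset, tab,
                             sd)
  agg_n <- stats::aggregate(entropy ~ cell_type + age_group + subset, tab,
                            length)
  summary <- agg_mean
  names(summary)[4] <- "mean"
  summary$sd <- agg_sd$entropy
  summary$n <- agg_n$entropy
  structure(tab, summary = summary,
            class = c("EntropyTable", "data.frame"))
}

#' Compare structural entropy between young and old cells
#'
#' Reports the old-minus-young mean entropy difference, per-group mean, sd
#' and n, and a two-sided Mann-Whitney U test (exact where sample sizes
#' permit, the `stats::wilcox.test` default).
#'
#' @param table An `EntropyTable`.
#' @param cell_type Cell type to compare.
#' @param subset Subset label (default `"all-genes"`).
#' @return List with `cell_type`, `subset`, per-group stats, `mean_diff`
#'   (old - young), `statistic` (U) and `p_value`.
#' @export
compare_groups <- function(table, cell_type, subset = "all-genes") {
  stopifnot(inherits(table, "EntropyTable"))
  sub <- table[table$cell_type == cell_type & table$subset == subset, ]
  young <- sub$entropy[sub$age_group == "young"]
  old <- sub$entropy[sub$age_group == "old"]
  if (length(young) < 2 || length(old) < 2)
    stop("both groups need at least 2 cells")
  wt <- suppressWarnings(wilcox.test(old, young, alternative = "two.sided"))
  list(cell_type = cell_type, subset = subset,
       n_young = length(young), n_old = length(old),
       mean_young = mean(young), mean_old = mean(old),
       sd_young = sd(young), sd_old = sd(old),
       mean_diff = mean(old) - mean(young),
       statistic = unname(wt$statistic), p_value = wt$p.value)
}

#' Write an entropy table and its group summary
#' @param table An `EntropyTable`.
#' @param path Tidy per-cell TSV output.
#' @param summary_path Optional per-group summary TSV.
#' @return `path`, invisibly.
#' @export
write_entropy <- function(table, path, summary_path = NULL) {
  stopifnot(inherits(table, "EntropyTable"))
  write.table(table, path, sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(summary_path))
    write.table(attr(table, "summary"), summary_path, sep = "\t",
                row.names = FALSE, quote = FALSE)
  invisible(path)
}
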