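#' Marker genes by per-gene two-sample t-test
#'
#' Tests every gene (row) of a genes x cells matrix for a mean difference
#' between young and old cells. Welch's unequal-variance t-test is the
#' default (age groups are typically strongly unbalanced); the pooled
#' Student variant is available behind `var_equal = TRUE`. Genes are ranked
#' by ascending p-value, ties broken by descending `|t|`, then gene id;
#' Benjamini-Hochberg adjusted p-values are attached for downstream
#' thresholding, while the top-k lists use the raw-p ranking. Genes with
#' zero variance in both groups have an undefined t and are assigned
#' `p = 1`; they are recorded in `attr(, "degenerate_genes")`.
#'
#' @param matrix Numeric genes x cells matrix (GEM values or GIM values)
#'   with gene-id rownames.
#' @param labels Character vector (`"young"`/`"old"`) per cell.
#' @param k Number of top markers per direction (default 10).
#' @param var_equal Use the pooled-variance Student test instead of Welch.
#' @param matrix_kind Label stored on the result, conventionally `"GEM"` or
#'   `"GIM"`.
#' @return A `MarkerResult` data frame (`gene_id`, `mean_young`,
#'   `mean_old`, `t_statistic`, `df`, `p_value`, `adjusted_p`, `direction`,
#'   `rank`), ordered by rank, with attributes `top_up_in_old`,
#'   `top_up_in_young` (character vectors of length <= k) and
#'   `matrix_kind`.
#' @export
t_test_markers <- function(matrix, labels, k = 10L, var_equal = FALSE,
                           matrix_kind = "GEM") {
  matrix <- as.matrix(matrix)
  if (is.null(rownames(matrix)))
    rownames(matrix) <- paste0("g", seq_len(nrow(matrix)))
  if (length(labels) != ncol(matrix))
    stop("labels must have one entry per cell")
  if (!all(labels %in% c("young", "old")))
    stop("labels must be 'young' or 'old'")
  y <- matrix[, labels == "young", drop = FALSE]
  o <- matrix[, labels == "old", drop = FALSE]
  n1 <- ncol(y); n2 <- ncol(o)
  if (n1 < 2 || n2 < 2) stop("both groups need at least 2 cells")
  if (k > nrow(matrix)) stop("k exceeds the number of genes")
  m1 <- rowMeans(y); m2 <- rowMeans(o)
  v1 <- rowSums((y - m1)^2) / (n1 - 1)
  v2 <- rowSums((o - m2)^2) / (n2 - 1)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, nrow(matrix))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  tstat <- (m2 - m1) / se
  p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  degenerate <- !is.finite(tstat)            # zero variance in both groups
  tstat[degenerate] <- NA_real_
  df[degenerate] <- NA_real_
  p[degenerate] <- 1
  res <- data.frame(
    gene_id = rownames(matrix), mean_young = m1, mean_old = m2,
    t_statistic = tstat, df = df, p_value = p,
    adjusted_p = p.adjust(p, "BH"),
    direction = ifelse(m2 > m1, "up-in-old", "up-in-young"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  absT <- ifelse(is.na(res$t_statistic), -Inf, abs(res$t_statistic))
  ord <- order(res$p_value, -absT, res$gene_id)
  res <- res[ord, ]
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  structure(res,
            top_up_in_old = utils::head(
              res$gene_id[res$direction == "up-in-old"], k),
            top_up_in_young = utils::head(
              res$gene_id[res$direction == "up-in-young"], k),
            k = as.integer(k), matrix_kind = matrix_kind,
            degenerate_genes = rownames(matrix)[degenerate],
            class = c("MarkerResult", "data.frame"))
}

#' Top-k marker gene ids of a MarkerResult
#' @param markers A `MarkerResult`.
#' @param direction `"up-in-old"`, `"up-in-young"`, or `"both"` (combined,
#'   by rank).
#' @param k Number of genes (default: the `k` the result was built with;
#'   for `"both"`, the top `k` overall regardless of direction).
#' @return Character vector of gene ids.
#' @export
top_markers <- function(markers, direction = c("both", "up-in-old",
                                               "up-in-young"),
                        k = attr(markers, "k")) {
  stopifnot(inherits(markers, "MarkerResult"))
  direction <- match.arg(direction)
  if (direction == "both") return(utils::head(markers$gene_id, k))
  utils::head(markers$gene_id[markers$direction == direction], k)
}

#' Dark genes: significant in the network space, not in expression
#'
#' A gene is "dark" when it separates young from old cells in the
#' gene importance matrix (adjusted p below `alpha_net` in the GIM test)
#' while showing no detectable expression difference (adjusted p at or
#' above `alpha_expr` in the GEM test). Such genes change their network
#' neighborhood rather than their marginal expression.
#'
#' @param gim_markers `MarkerResult` computed on the GIM.
#' @param gem_markers `MarkerResult` computed on the GEM (same genes, same
#'   labels).
#' @param alpha_net Adjusted-p threshold for the network-level test
#'   (default 0.05).
#' @param alpha_expr Adjusted-p threshold for the expression-level test
#'   (default 0.05).
#' @return Data frame of dark genes ordered by GIM significance, with both
#'   tests' statistics (`gim_p`, `gim_adjusted_p`, `gem_p`,
#'   `gem_adjusted_p`, `gim_direction`).
#' @export
dark_genes <- function(gim_markers, gem_markers, alpha_net = 0.05,
                       alpha_expr = 0.05) {
  stopifnot(inherits(gim_markers, "MarkerResult"),
            inherits(gem_markers, "MarkerResult"))
  if (!setequal(gim_markers$gene_id, gem_markers$gene_id))
    stop("marker results cover different gene universes")
  gem_at <- gem_markers[match(gim_markers$gene_id, gem_markers$gene_id), ]
  keep <- gim_markers$adjusted_p < alpha_net &
    gem_at$adjusted_p >= alpha_expr
  out <- data.frame(
    gene_id = gim_markers$gene_id,
    gim_t = gim_markers$t_statistic, gim_p = gim_markers$p_value,
    gim_adjusted_p = gim_markers$adjusted_p,
    gim_direction = gim_markers$direction,
    gem_t = gem_at$t_statistic, gem_p = gem_at$p_value,
    gem_adjusted_p = gem_at$adjusted_p,
    stringsAsFactors = FALSE
  )[keep, ]
  out <- out[order(out$gim_adjusted_p, out$gim_p, out$gene_id), ]
  rownames(out) <- NULL
  out
}
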