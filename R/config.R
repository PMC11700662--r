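#' Pipeline configuration
#'
#' Collects the tunable parameters of the whole pipeline in one validated
#' object. Defaults follow the method's fixed constants where stated
#' (neighborhood box fraction 0.1, per-pair significance level 0.01, at most
#' 100 PageRank iterations with convergence accuracy 1e-6); parameters the
#' method leaves open (damping factor, log base, edge rule, PageRank variant)
#' are exposed here with conventional defaults.
#'
#' @param box_fraction Fraction of cells in each gene's expression
#'   neighborhood; the box holds `round(box_fraction * n_C)` cells. Default
#'   0.1.
#' @param alpha Per-pair significance level for calling an edge. Default 0.01.
#' @param damping PageRank damping factor `d` in (0, 1). Default 0.85, the
#'   canonical choice.
#' @param max_iter Maximum PageRank iterations. Default 100.
#' @param tol PageRank convergence accuracy (max absolute per-gene change).
#'   Default 1e-6.
#' @param top_k Number of marker genes per direction; 10, 50 and 100 are the
#'   conventional sizes. Default 10.
#' @param log_base Base of the logarithm used in preprocessing and entropy.
#'   Default `exp(1)` (natural log).
#' @param seed Integer seed used wherever randomness enters (clustering
#'   restarts, synthetic data).
#' @param edge_rule `"z"` (default): upper-tail test of the neighborhood
#'   overlap count against its exact null distribution at level `alpha`.
#'   `"literal-rho"`: threshold the independence statistic rho directly at
#'   `alpha` (the literal reading of the threshold rule; not calibrated as a
#'   test). See [build_cell_network()].
#' @param pagerank_variant `"donor"` (default) or `"literal-eq3"`; see
#'   [weighted_pagerank()].
#' @param scale_target Per-cell library-size target used by
#'   [preprocess_gem()]. Default 10000.
#' @param alpha_net,alpha_expr Adjusted-p thresholds used by [dark_genes()].
#' @return A list of class `"PipelineConfig"`.
#' @export
#' @examples
#' cfg <- pipeline_config(seed = 7)
#' cfg$box_fraction
pipeline_config <- function(box_fraction = 0.1, alpha = 0.01, damping = 0.85,
                            max_iter = 100L, tol = 1e-6, top_k = 10L,
                            log_base = exp(1), seed = 1L,
                            edge_rule = c("z", "literal-rho"),
                            pagerank_variant = c("donor", "literal-eq3"),
                            scale_target = 1e4,
                            alpha_net = 0.05, alpha_expr = 0.05) {
  edge_rule <- match.arg(edge_rule)
  pagerank_variant <- match.arg(pagerank_variant)
  stopifnot(
    is.numeric(box_fraction), length(box_fraction) == 1L,
    box_fraction > 0, box_fraction < 1,
    is.numeric(alpha), alpha > 0, alpha < 1,
    is.numeric(damping), damping > 0, damping < 1,
    max_iter >= 1, tol > 0, top_k >= 1, log_base > 0, log_base != 1,
    scale_target > 0, alpha_net > 0, alpha_net <= 1,
    alpha_expr > 0, alpha_expr <= 1
  )
  structure(list(
    box_fraction = box_fraction, alpha = alpha, damping = damping,
    max_iter = as.integer(max_iter), tol = tol, top_k = as.integer(top_k),
    log_base = log_base, seed = as.integer(seed), edge_rule = edge_rule,
    pagerank_variant = pagerank_variant, scale_target = scale_target,
    alpha_net = alpha_net, alpha_expr = alpha_expr
  ), class = "PipelineConfig")
}

#' @export
print.PipelineConfig <- function(x, ...) {
  cat("PipelineConfig\n")
  for (nm in names(x)) cat(sprintf("  %-17s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
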