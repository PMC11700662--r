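# Independent oracle implementations used to cross-check the package.
# These are deliberately written from scratch (plain R, no calls into the
# code paths they verify).

# value-nearest neighborhood of size m around cell k, by exhaustive scan:
# sort all cells by (value, index), walk outward from k's position taking
# the closer side (ties -> lower rank).
oracle_neighborhood <- function(x, k, m) {
  n <- length(x)
  ord <- order(x, seq_len(n))
  v <- x[ord]
  p <- which(ord == k)
  chosen <- p
  lo <- p
  hi <- p
  while (length(chosen) < m) {
    left_ok <- lo > 1
    right_ok <- hi < n
    take_left <- if (left_ok && right_ok) {
      (v[p] - v[lo - 1]) <= (v[hi + 1] - v[p])
    } else left_ok
    if (take_left) {
      lo <- lo - 1
      chosen <- c(chosen, lo)
    } else {
      hi <- hi + 1
      chosen <- c(chosen, hi)
    }
  }
  sort(ord[chosen])
}

# degree-distribution entropy straight from an edge list
oracle_entropy <- function(i, j, n_nodes, log_base = exp(1)) {
  deg <- rep(0, n_nodes)
  for (e in seq_along(i)) {
    deg[i[e]] <- deg[i[e]] + 1
    deg[j[e]] <- deg[j[e]] + 1
  }
  p <- as.vector(table(deg)) / n_nodes
  -sum(p * log(p, base = log_base))
}

# PageRank fixed point by direct linear solve: x = (1-d) 1 + d M x
oracle_pagerank_solve <- function(M, d) {
  n <- nrow(M)
  solve(diag(n) - d * M, rep(1 - d, n))
}

# pair-counting clustering metrics from first principles: iterate over all
# pairs of observations
oracle_pair_metrics <- function(a, b) {
  n <- length(a)
  ss <- sd_ <- ds <- dd <- 0
  for (p in seq_len(n - 1)) for (q in seq((p + 1), n)) {
    sa <- a[p] == a[q]
    sb <- b[p] == b[q]
    if (sa && sb) ss <- ss + 1
    else if (sa && !sb) sd_ <- sd_ + 1
    else if (!sa && sb) ds <- ds + 1
    else dd <- dd + 1
  }
  tot <- ss + sd_ + ds + dd
  exp_ss <- (ss + sd_) * (ss + ds) / tot
  max_ss <- ((ss + sd_) + (ss + ds)) / 2
  ari <- if (max_ss == exp_ss) 1 else (ss - exp_ss) / (max_ss - exp_ss)
  fmi <- if ((ss + sd_) == 0 || (ss + ds) == 0) 0 else
    ss / sqrt((ss + sd_) * (ss + ds))
  list(ari = ari, fmi = fmi)
}

# NMI from explicit category loops
oracle_nmi <- function(a, b) {
  ua <- unique(a)
  ub <- unique(b)
  n <- length(a)
  mi <- 0
  for (x in ua) for (y in ub) {
    pxy <- sum(a == x & b == y) / n
    if (pxy > 0) mi <- mi + pxy * log(pxy / (sum(a == x) / n *
                                               sum(b == y) / n))
  }
  ha <- -sum(sapply(ua, function(x) {
    p <- sum(a == x) / n
    p * log(p)
  }))
  hb <- -sum(sapply(ub, function(y) {
    p <- sum(b == y) / n
    p * log(p)
  }))
  if (ha == 0 && hb == 0) return(1)
  if (ha == 0 || hb == 0) return(0)
  mi / ((ha + hb) / 2)
}

# Welch t and p for one gene, textbook formulas
oracle_welch <- function(x, y) {
  v1 <- var(x) / length(x)
  v2 <- var(y) / length(y)
  t <- (mean(y) - mean(x)) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (length(x) - 1) + v2^2 / (length(y) - 1))
  list(t = t, p = 2 * pt(abs(t), df, lower.tail = FALSE))
}

# exact two-sided Mann-Whitney p by full enumeration of group assignments
oracle_mannwhitney <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  idx <- utils::combn(length(pooled), n1)
  ustat <- function(a, b) {
    u <- 0
    for (xi in a) u <- u + sum(xi > b) + 0.5 * sum(xi == b)
    u
  }
  obs <- ustat(x, y)
  mu <- n1 * length(y) / 2
  us <- apply(idx, 2, function(s) ustat(pooled[s], pooled[-s]))
  list(u = obs, p = mean(abs(us - mu) >= abs(obs - mu) - 1e-12))
}

# small hand-made CellNetwork / CellNetworkSet fixtures
make_cell_network <- function(cell_id, gene_ids, edges) {
  # edges: 2-column matrix of gene indices (i < j)
  edges <- matrix(as.integer(edges), ncol = 2)
  structure(list(
    cell_id = cell_id,
    edges = data.frame(gene_i = gene_ids[edges[, 1]],
                       gene_j = gene_ids[edges[, 2]],
                       n_ij = rep(NA_integer_, nrow(edges)),
                       z = rep(NA_real_, nrow(edges)),
                       stringsAsFactors = FALSE),
    i = edges[, 1], j = edges[, 2], n_genes = length(gene_ids),
    gene_ids = gene_ids, m = NA_integer_, n_C = NA_integer_),
    class = "CellNetwork")
}

make_network_set <- function(gene_ids, edge_list) {
  # edge_list: named list cell_id -> 2-column gene-index matrix
  nets <- lapply(names(edge_list), function(cid)
    make_cell_network(cid, gene_ids, edge_list[[cid]]))
  structure(list(networks = nets, cell_ids = names(edge_list),
                 gene_ids = gene_ids, m = NA_integer_,
                 n_C = length(edge_list), edge_rule = "z", alpha = 0.01,
                 box_fraction = 0.1, min_n_ij = NA,
                 zero_variance = character()),
            class = "CellNetworkSet")
}

# quick raw GEM around a value matrix
make_gem <- function(values, age = NULL, type = "t", preprocessed = FALSE) {
  n <- ncol(values)
  if (is.null(age)) age <- rep(c("young", "old"), length.out = n)
  if (is.null(colnames(values))) colnames(values) <- paste0("c", seq_len(n))
  if (is.null(rownames(values)))
    rownames(values) <- paste0("g", seq_len(nrow(values)))
  expression_matrix(values, cell_meta = data.frame(
    cell_id = colnames(values), age_group = age, cell_type = type,
    stringsAsFactors = FALSE), preprocessed = preprocessed)
}
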