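genes5 <- paste0("g", 1:5)

test_that("degree distributions follow hand counts on small graphs", {
  # 3-node path a-b, b-c on a 3-gene subset
  net <- make_cell_network("c1", genes5, rbind(c(1, 2), c(2, 3)))
  dd <- degree_distribution(net, c("g1", "g2", "g3"))
  expect_identical(dd$degrees, c(1L, 2L))
  expect_equal(dd$probs, c(2 / 3, 1 / 3))
  expect_equal(sum(dd$counts), dd$n_genes)
  # 4-node cycle: regular, p(2) = 1
  cyc <- make_cell_network("c1", genes5,
                           rbind(c(1, 2), c(2, 3), c(3, 4), c(1, 4)))
  ddc <- degree_distribution(cyc, paste0("g", 1:4))
  expect_equal(ddc$probs, 1)
  # empty network on 5 genes: p(0) = 1
  empty <- make_cell_network("c1", genes5, matrix(integer(), ncol = 2))
  dde <- degree_distribution(empty)
  expect_identical(dde$degrees, 0L)
  expect_equal(dde$probs, 1)
  expect_error(degree_distribution(net, character()), "non-empty")
  expect_error(degree_distribution(net, "gX"), "unknown gene")
})

test_that("induced subnetworks drop edges crossing the subset boundary", {
  net <- make_cell_network("c1", genes5, rbind(c(1, 2), c(2, 3), c(4, 5)))
  dd <- degree_distribution(net, c("g1", "g2", "g4"))
  # only edge g1-g2 survives; g4's partner g5 is outside
  expect_equal(unname(dd$degree_sequence), c(1L, 1L, 0L))
})

test_that("structural entropy has its closed forms", {
  # any regular graph: one degree value, H = 0
  cyc <- make_cell_network("c1", genes5,
                           rbind(c(1, 2), c(2, 3), c(3, 4), c(1, 4)))
  expect_equal(structural_entropy(degree_distribution(cyc, paste0("g", 1:4))),
               0)
  # p = (1/2, 1/2): H = ln 2
  path4 <- make_cell_network("c1", genes5,
                             rbind(c(1, 2), c(2, 3), c(3, 4)))
  expect_equal(structural_entropy(degree_distribution(path4,
                                                      paste0("g", 1:4))),
               log(2))
  # base-2 logs rescale
  expect_equal(structural_entropy(degree_distribution(path4,
                                                      paste0("g", 1:4)),
                                  log_base = 2), 1)
})

test_that("entropy matches a from-scratch tabulation oracle on random graphs", {
  set.seed(12)
  for (rep in 1:25) {
    n <- sample(5:50, 1)
    gene_ids <- paste0("g", seq_len(n))
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    sel <- pairs[runif(nrow(pairs)) < 0.15, , drop = FALSE]
    net <- make_cell_network("c1", gene_ids, sel)
    got <- structural_entropy(degree_distribution(net))
    expect_equal(got, oracle_entropy(sel[, 1], sel[, 2], n))
    # bounded by log of the support size
    supp <- length(unique(tabulate(c(sel[, 1], sel[, 2]), nbins = n)))
    expect_lte(got, log(supp) + 1e-12)
    expect_gte(got, 0)
  }
})

test_that("entropy is invariant to gene relabeling", {
  set.seed(19)
  n <- 12
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  sel <- pairs[sample(nrow(pairs), 14), ]
  perm <- sample(n)
  net1 <- make_cell_network("c1", paste0("g", 1:n), sel)
  net2 <- make_cell_network("c1", paste0("g", 1:n),
                            cbind(perm[sel[, 1]], perm[sel[, 2]]))
  expect_equal(structural_entropy(degree_distribution(net1)),
               structural_entropy(degree_distribution(net2)))
})

test_that("per-cell entropy tables carry labels, subsets and summaries", {
  genes <- paste0("g", 1:6)
  set <- make_network_set(genes, list(
    y1 = rbind(c(1, 2), c(2, 3)), y2 = rbind(c(1, 2), c(2, 3)),
    o1 = rbind(c(1, 2)), o2 = rbind(c(4, 5), c(5, 6), c(4, 6))))
  meta <- data.frame(cell_id = c("y1", "y2", "o1", "o2"),
                     age_group = c("young", "young", "old", "old"),
                     cell_type = "t")
  et <- per_cell_entropy(set, meta,
                         marker_sets = list(m3 = c("g1", "g2", "g3")))
  expect_identical(nrow(et), 4L * 2L)        # cells x subsets
  expect_setequal(unique(et$subset), c("m3", "all-genes"))
  # identical cells: identical entropies
  expect_equal(et$entropy[et$cell_id == "y1"],
               et$entropy[et$cell_id == "y2"])
  smry <- attr(et, "summary")
  expect_true(all(c("mean", "sd", "n") %in% names(smry)))
  expect_equal(sum(smry$n), 8)
  expect_error(per_cell_entropy(set, meta, list(`all-genes` = genes)),
               "reserved")
})

entropy_table <- function(values, age) {
  structure(data.frame(cell_id = paste0("c", seq_along(values)),
                       cell_type = "t", age_group = age,
                       subset = "all-genes", entropy = values,
                       stringsAsFactors = FALSE),
            class = c("EntropyTable", "data.frame"))
}

test_that("group comparison matches the exact permutation oracle", {
  et <- entropy_table(c(1, 2, 3, 4, 5, 6),
                      rep(c("young", "old"), each = 3))
  cmp <- compare_groups(et, "t")
  oracle <- oracle_mannwhitney(c(4, 5, 6), c(1, 2, 3))
  expect_equal(cmp$statistic, oracle$u)
  expect_equal(cmp$p_value, oracle$p, tolerance = 1e-12)
  expect_equal(cmp$mean_diff, 3)
  # a scrambled variant, still tie-free
  et2 <- entropy_table(c(2.5, 7, 1, 4, 6, 3, 5.5, 0.5),
                       rep(c("young", "old"), 4))
  cmp2 <- compare_groups(et2, "t")
  o2 <- oracle_mannwhitney(et2$entropy[et2$age_group == "old"],
                           et2$entropy[et2$age_group == "young"])
  expect_equal(cmp2$statistic, o2$u)
  expect_equal(cmp2$p_value, o2$p, tolerance = 1e-12)
  # identical groups: zero mean difference
  et3 <- entropy_table(c(1, 2, 1, 2), c("young", "young", "old", "old"))
  expect_equal(compare_groups(et3, "t")$mean_diff, 0)
  expect_error(compare_groups(entropy_table(1:3, c("young", "old", "old")),
                              "t"),
               "at least 2 cells")
})

test_that("entropy tables round-trip through their TSV export", {
  genes <- paste0("g", 1:4)
  set <- make_network_set(genes, list(a = rbind(c(1, 2)),
                                      b = rbind(c(1, 2), c(2, 3))))
  meta <- data.frame(cell_id = c("a", "b"),
                     age_group = c("young", "old"), cell_type = "t")
  et <- per_cell_entropy(set, meta)
  tmp <- withr::local_tempdir()
  write_entropy(et, file.path(tmp, "e.tsv"), file.path(tmp, "s.tsv"))
  back <- read.delim(file.path(tmp, "e.tsv"))
  expect_equal(back$entropy, et$entropy)
  expect_true(file.exists(file.path(tmp, "s.tsv")))
})
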