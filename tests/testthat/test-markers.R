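test_that("a strongly shifted gene ranks first", {
  set.seed(31)
  mat <- matrix(rnorm(100 * 60), nrow = 100,
                dimnames = list(paste0("g", 1:100), NULL))
  labels <- rep(c("young", "old"), each = 30)
  mat[17, labels == "old"] <- mat[17, labels == "old"] + 5
  res <- t_test_markers(mat, labels, k = 10)
  expect_identical(res$gene_id[1], "g17")
  expect_identical(res$direction[1], "up-in-old")
  expect_identical(attr(res, "top_up_in_old")[1], "g17")
})

test_that("welch statistics match t.test and the textbook oracle", {
  set.seed(32)
  mat <- matrix(rnorm(20 * 23, sd = rep(c(1, 3), 10)), nrow = 20,
                dimnames = list(paste0("g", 1:20), NULL))
  labels <- rep(c("young", "old"), c(9, 14))
  res <- t_test_markers(mat, labels, k = 5)
  for (g in c("g3", "g11", "g20")) {
    x <- mat[g, labels == "young"]
    y <- mat[g, labels == "old"]
    ref <- t.test(y, x)
    ora <- oracle_welch(x, y)
    row <- res[res$gene_id == g, ]
    expect_equal(row$t_statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(row$p_value, ref$p.value, tolerance = 1e-10)
    expect_equal(row$t_statistic, ora$t, tolerance = 1e-10)
    expect_equal(row$p_value, ora$p, tolerance = 1e-10)
  }
  expect_equal(res$adjusted_p, p.adjust(res$p_value, "BH"))
  expect_true(all(res$adjusted_p >= res$p_value - 1e-15))
  # pooled variant agrees with var.equal t.test
  pooled <- t_test_markers(mat, labels, k = 5, var_equal = TRUE)
  ref2 <- t.test(mat["g3", labels == "old"], mat["g3", labels == "young"],
                 var.equal = TRUE)
  expect_equal(pooled$t_statistic[pooled$gene_id == "g3"],
               unname(ref2$statistic), tolerance = 1e-10)
})

test_that("null labels give a calibrated p-value distribution", {
  set.seed(33)
  mat <- matrix(rnorm(1000 * 80), nrow = 1000,
                dimnames = list(paste0("g", 1:1000), NULL))
  labels <- sample(rep(c("young", "old"), each = 40))
  res <- t_test_markers(mat, labels, k = 10)
  frac <- mean(res$p_value < 0.05)
  expect_lt(abs(frac - 0.05), 0.025)
})

test_that("ranking is a deterministic permutation; k = n_G partitions", {
  set.seed(34)
  mat <- matrix(rnorm(30 * 20), nrow = 30,
                dimnames = list(paste0("g", 1:30), NULL))
  labels <- rep(c("young", "old"), each = 10)
  res <- t_test_markers(mat, labels, k = 30)
  expect_setequal(res$rank, 1:30)
  res2 <- t_test_markers(mat, labels, k = 30)
  expect_identical(res$gene_id, res2$gene_id)
  both <- c(attr(res, "top_up_in_old"), attr(res, "top_up_in_young"))
  expect_setequal(both, res$gene_id)
  expect_error(t_test_markers(mat, labels, k = 31), "exceeds")
  expect_error(t_test_markers(mat, rep("young", 20), k = 2),
               "at least 2 cells")
})

test_that("zero-variance-in-both-groups genes are assigned p = 1", {
  mat <- rbind(g1 = c(1, 1, 1, 1), g2 = c(1, 2, 3, 4))
  labels <- c("young", "young", "old", "old")
  res <- t_test_markers(mat, labels, k = 1)
  row <- res[res$gene_id == "g1", ]
  expect_true(is.na(row$t_statistic))
  expect_equal(row$p_value, 1)
  expect_identical(attr(res, "degenerate_genes"), "g1")
})

test_that("dark genes require network significance without expression change", {
  set.seed(35)
  n <- 60
  labels <- rep(c("young", "old"), each = 20)
  gim <- matrix(rnorm(n * 40), nrow = n,
                dimnames = list(paste0("g", 1:n), NULL))
  gem <- matrix(rnorm(n * 40), nrow = n,
                dimnames = list(paste0("g", 1:n), NULL))
  gim[1, labels == "old"] <- gim[1, labels == "old"] + 6  # dark
  gim[2, labels == "old"] <- gim[2, labels == "old"] + 6  # sig in both
  gem[2, labels == "old"] <- gem[2, labels == "old"] + 6
  mk_gim <- t_test_markers(gim, labels, k = 5, matrix_kind = "GIM")
  mk_gem <- t_test_markers(gem, labels, k = 5, matrix_kind = "GEM")
  dk <- dark_genes(mk_gim, mk_gem)
  expect_true("g1" %in% dk$gene_id)
  expect_false("g2" %in% dk$gene_id)      # significant in both: excluded
  # no GIM-significant genes: empty result
  null_gim <- t_test_markers(
    matrix(rnorm(n * 40), nrow = n,
           dimnames = list(paste0("g", 1:n), NULL)), labels, k = 5)
  expect_identical(nrow(dark_genes(null_gim, mk_gem)), 0L)
  # universe mismatch refused
  small <- t_test_markers(gim[1:10, ], labels, k = 2)
  expect_error(dark_genes(small, mk_gem), "different gene universes")
})

test_that("the dark set is monotone in the network threshold", {
  set.seed(36)
  n <- 80
  labels <- rep(c("young", "old"), each = 25)
  gim <- matrix(rnorm(n * 50), nrow = n,
                dimnames = list(paste0("g", 1:n), NULL))
  gim[1:6, labels == "old"] <- gim[1:6, labels == "old"] +
    seq(0.5, 3, length.out = 6)
  gem <- matrix(rnorm(n * 50), nrow = n,
                dimnames = list(paste0("g", 1:n), NULL))
  mk_gim <- t_test_markers(gim, labels, k = 5)
  mk_gem <- t_test_markers(gem, labels, k = 5)
  loose <- dark_genes(mk_gim, mk_gem, alpha_net = 0.2)
  strict <- dark_genes(mk_gim, mk_gem, alpha_net = 0.01)
  expect_true(all(strict$gene_id %in% loose$gene_id))
})
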