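test_that("rho follows its defining arithmetic", {
  expect_equal(rho_statistic(5, 10, 10, 100), 0.04)
  expect_equal(rho_statistic(10, 10, 10, 100), 0.09)
  # exact independence: n_ij = n_i n_j / n_C
  expect_equal(rho_statistic(1, 10, 10, 100), 0)
  expect_error(rho_statistic(5, 10, 10, 0), "n_C")
  expect_error(rho_statistic(11, 10, 10, 100), "invalid")
})

test_that("normalized statistic matches its closed form", {
  sigma <- sqrt(10 * 10 * 90 * 90 / (100^4 * 99))
  expect_equal(normalized_statistic(0.04, 10, 10, 100), 0.04 / sigma)
  expect_equal(normalized_statistic(0, 10, 10, 100), 0)
  expect_error(normalized_statistic(0.1, 0, 10, 100), "undefined variance")
  expect_error(normalized_statistic(0.1, 10, 100, 100), "undefined variance")
})

test_that("neighborhood counts match the exhaustive-scan oracle", {
  set.seed(7)
  for (rep in 1:30) {
    n_C <- sample(20:200, 1)
    gem <- preprocess_gem(make_gem(matrix(rpois(8 * n_C, 20), nrow = 8)))
    k <- sample(n_C, 1)
    ij <- sample(8, 2)
    got <- neighborhood_counts(gem, k, ij[1], ij[2])
    m <- box_size(n_C, 0.1)
    oi <- oracle_neighborhood(gem$values[ij[1], ], k, m)
    oj <- oracle_neighborhood(gem$values[ij[2], ], k, m)
    expect_identical(sort(got$cells_i), oi)
    expect_identical(sort(got$cells_j), oj)
    expect_identical(got$n_ij, length(intersect(oi, oj)))
    expect_identical(got$n_i, m)
  }
})

test_that("degenerate and duplicate neighborhoods behave as sets", {
  # n_C = 10 at box fraction 0.1: the focal cell alone
  gem <- preprocess_gem(make_gem(matrix(rpois(30, 50), nrow = 3)))
  got <- neighborhood_counts(gem, 4, 1, 2)
  expect_identical(got$n_i, 1L)
  expect_identical(got$n_ij, 1L)
  expect_identical(got$cells_i, 4L)
  # duplicated gene row: intersection of equal sets
  vals <- matrix(rpois(100, 30), nrow = 2)
  vals[2, ] <- vals[1, ]
  gem2 <- preprocess_gem(make_gem(vals))
  got2 <- neighborhood_counts(gem2, 17, 1, 2)
  expect_identical(got2$n_ij, got2$n_i)
})

test_that("edge thresholds encode the configured rule", {
  # literal rho >= alpha  <=>  n_ij >= n_C alpha + m^2 / n_C
  expect_identical(edge_count_threshold(100, 10, 0.01, "literal-rho"), 2)
  # calibrated rule centres on the shared-cell hypergeometric null
  m <- 50; n_C <- 500
  mu0 <- 1 + 49^2 / 499
  sd0 <- sqrt(49^2 * 450^2 / (499^2 * 498))
  expect_identical(edge_count_threshold(n_C, m, 0.01, "z"),
                   ceiling(mu0 + qnorm(0.99) * sd0 - 1e-9))
  expect_identical(edge_count_threshold(10, 1, 0.01, "z"), Inf)
})

test_that("the centered overlap z-score is standard normal under independence", {
  # Monte-Carlo null: continuous independent genes; a fresh gene pair per
  # draw keeps the overlap counts essentially independent
  set.seed(3)
  n_C <- 1000
  m <- box_size(n_C)
  gem <- preprocess_gem(make_gem(matrix(rexp(40 * n_C), nrow = 40)))
  mu0 <- 1 + (m - 1)^2 / (n_C - 1)
  sd0 <- sqrt((m - 1)^2 * (n_C - m)^2 / ((n_C - 1)^2 * (n_C - 2)))
  pairs <- t(utils::combn(40, 2))
  sel <- pairs[sample(nrow(pairs), 300), ]
  zs <- vapply(1:300, function(r) {
    k <- sample(n_C, 1)
    (neighborhood_counts(gem, k, sel[r, 1], sel[r, 2])$n_ij - mu0) / sd0
  }, 1)
  expect_lt(abs(mean(zs)), 0.15)
  expect_lt(abs(sd(zs) - 1), 0.15)
})

test_that("per-cell networks are symmetric objects with excluded constants", {
  set.seed(5)
  vals <- log1p(matrix(rpois(50 * 100, 20), nrow = 50))
  vals[7, ] <- log1p(4)                # constant gene (preprocessed scale)
  gem <- make_gem(vals, preprocessed = TRUE)
  nets <- build_all_networks(gem, pipeline_config())
  expect_length(nets$networks, 100L)
  net <- nets$networks[[13]]
  adj <- as_adjacency(net)
  expect_equal(as.matrix(adj), t(as.matrix(adj)))
  expect_true(all(Matrix::diag(adj) == 0))
  expect_identical(n_edges(net), nrow(net$edges))
  # constant gene participates in no edge, and is reported
  expect_false(any(net$i == 7 | net$j == 7))
  expect_identical(nets$zero_variance, gem$gene_ids[7])
  # single-cell build agrees with the batch build
  expect_equal(build_cell_network(gem, 13)$edges, net$edges)
})

test_that("identical cells yield identical networks", {
  set.seed(8)
  vals <- matrix(rpois(20 * 60, 15), nrow = 20)
  vals[, 31] <- vals[, 2]
  gem <- preprocess_gem(make_gem(vals))
  nets <- build_all_networks(gem, pipeline_config())
  expect_equal(nets$networks[[2]]$edges[, c("gene_i", "gene_j", "n_ij")],
               nets$networks[[31]]$edges[, c("gene_i", "gene_j", "n_ij")])
})

test_that("a strongly correlated planted pair is detected in most cells", {
  # high baselines keep the realized correlation near the 0.95 target
  truth <- synthetic_truth(10, blocks_young = list(
    list(genes = 1:2, cor = 0.95)), blocks_old = list(
      list(genes = 1:2, cor = 0.95)),
    base_log_mean_range = c(log(50), log(200)), seed = 21)
  sim <- generate_gem(10, 250, truth)
  gem <- preprocess_gem(sim$gem)
  nets <- build_all_networks(gem, pipeline_config())
  planted <- mean(vapply(nets$networks, function(n)
    any(n$i == 1 & n$j == 2), TRUE))
  # present in the large majority of cells, against a 1% false-edge floor
  expect_gt(planted, 0.6)
  # independent background pairs fire at roughly alpha
  other <- vapply(nets$networks, function(n)
    sum(n$i >= 3 | n$j >= 3), 1)
  n_other_pairs <- choose(10, 2) - 1
  expect_lt(mean(other) / n_other_pairs, 0.04)
})

test_that("permuting one gene's values calibrates its edge rate to alpha", {
  set.seed(13)
  truth <- synthetic_truth(20, blocks_young = list(
    list(genes = 1:10, cor = 0.9)), blocks_old = list(
      list(genes = 1:10, cor = 0.9)), seed = 5)
  sim <- generate_gem(20, 150, truth)
  gem <- preprocess_gem(sim$gem)
  # break gene 1's links on the preprocessed scale, leaving the rest alone
  gem$values[1, ] <- sample(gem$values[1, ])
  nets <- build_all_networks(gem, pipeline_config())
  hits <- vapply(nets$networks, function(n) sum(n$i == 1 | n$j == 1), 1)
  rate <- sum(hits) / (19 * 300)
  # 99% binomial slack around alpha at 19 * 300 trials
  expect_lt(abs(rate - 0.01),
            qnorm(0.995) * sqrt(0.01 * 0.99 / (19 * 300)) + 0.006)
})

test_that("edge-list stores round-trip", {
  set.seed(9)
  gem <- preprocess_gem(make_gem(matrix(rpois(15 * 40, 25), nrow = 15)))
  nets <- build_all_networks(gem, pipeline_config())
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_networks(nets, tmp)
  back <- read_networks(tmp, nets$gene_ids, nets$cell_ids, nets$m,
                        nets$n_C)
  for (k in c(1, 20, 40))
    expect_equal(back$networks[[k]]$edges, nets$networks[[k]]$edges,
                 tolerance = 1e-12)
})
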