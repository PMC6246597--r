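fractions_tbl <- function(values) {
  # values: named list genus -> named numeric vector (sample -> fraction)
  purrr::imap(values, function(v, g) {
    tibble::tibble(raw_file = names(v), genus = g, fraction = unname(v))
  }) |> purrr::list_rbind()
}

test_that("two-group t-test handles null, strong and degenerate cases", {
  samples <- sprintf("s%d", 1:6)
  labels <- setNames(rep(c("G1", "G2"), each = 3), samples)

  same <- fractions_tbl(list(A = setNames(rep(0.25, 6), samples)))
  res <- two_group_t_test(same, labels)
  expect_equal(res$t_statistic, 0)
  expect_equal(res$p_value, 1)

  strong <- fractions_tbl(list(
    A = setNames(2^c(-1.0, -1.1, -0.9, 1.0, 0.9, 1.1), samples)))
  res <- two_group_t_test(strong, labels)
  expect_lt(res$p_value, 1e-3)
  expect_equal(res$log2_ratio, -2)
  # verify against the t-distribution CDF directly
  expect_equal(res$p_value, 2 * pt(-abs(res$t_statistic), df = 4),
               tolerance = 1e-12)

  # zero fractions are missing, not -Inf: genus with < 2 values per group
  # is reported untested
  sparse <- fractions_tbl(list(
    B = setNames(c(0.1, 0, 0, 0.2, 0.3, 0.1), samples)))
  res <- two_group_t_test(sparse, labels)
  expect_false(res$tested)
  expect_true(is.na(res$p_value))

  expect_error(two_group_t_test(same, labels[1:3]), "two groups")
  expect_error(two_group_t_test(same, setNames(c("G1", "G1", "G1", "G1",
                                                 "G1", "G2"), samples)),
               "at least two samples")
})

test_that("a spiked genus is detected with the correct sign", {
  detected <- vapply(1:10, function(seed) {
    cfg <- spike_effect(null_config(n_genera = 20, seed = seed),
                        "Genus001", 2)
    sim <- simulate_dataset(cfg)
    gf <- sim_fractions(sim)
    res <- two_group_t_test(gf, sim$truth$sample_groups)
    hit <- dplyr::filter(res, genus == "Genus001")
    hit$significant && hit$log2_ratio > 0
  }, logical(1))
  expect_gte(mean(detected), 0.9)
})

test_that("hierarchical clustering uses pairwise-complete Pearson distance", {
  set.seed(5)
  base <- matrix(rnorm(120), nrow = 30)
  mat <- cbind(a = base[, 1], b = base[, 1], c = -base[, 1], d = base[, 2])
  cl <- hierarchical_cluster(mat, k = 2)
  expect_equal(cl$dist["a", "b"], 0)        # duplicates: r = 1
  expect_equal(cl$dist["a", "c"], 2)        # anti-correlated: r = -1
  expect_equal(cl$tree$merge[1, ], c(-1, -2))  # duplicates merge first

  # pairs sharing < 3 entries are flagged and imputed
  sparse <- mat
  sparse[3:30, "d"] <- NA
  expect_warning(cl2 <- hierarchical_cluster(sparse), "share < 3")
  expect_equal(nrow(cl2$flagged_pairs), 3L)

  expect_error(hierarchical_cluster(mat[, 1, drop = FALSE]), "two samples")
})

test_that("clustering is invariant to sample input order", {
  sim <- simulate_dataset(sim_config(seed = 19))
  mat <- log2_median_normalize(min_half_filter(lfq_matrix(sim$protein_groups)))
  cl1 <- hierarchical_cluster(mat)
  set.seed(1); perm <- sample(ncol(mat))
  cl2 <- hierarchical_cluster(mat[, perm])
  expect_equal(sort(cl1$tree$height), sort(cl2$tree$height))
  # same flat partition up to label permutation
  g1 <- cl1$groups[colnames(mat)]
  g2 <- cl2$groups[colnames(mat)]
  expect_equal(mclust::adjustedRandIndex(g1, g2), 1)
})

test_that("percent scaling truncates toward zero after multiplying by 1e6", {
  expect_equal(scale_percent_to_counts(0), 0)
  expect_equal(scale_percent_to_counts(0.1234567), 123456)
  expect_equal(scale_percent_to_counts(100.0), 1e8)
  expect_error(scale_percent_to_counts(-0.1), "non-negative")
})

test_that("Bray-Curtis matches the hand formula and the double-loop oracle", {
  m <- rbind(a = c(6, 4), b = c(2, 8), c = c(6, 4), d = c(0, 10))
  bc <- bray_curtis(m)
  expect_equal(bc["a", "b"], 0.4)           # 1 - 2*6/20
  expect_equal(bc["a", "c"], 0)             # identical vectors
  disjoint <- rbind(x = c(5, 0), y = c(0, 7))
  expect_equal(bray_curtis(disjoint)["x", "y"], 1)

  set.seed(33)
  for (i in 1:5) {
    counts <- matrix(rpois(80, 40), nrow = 10, ncol = 8,
                     dimnames = list(sprintf("s%d", 1:10), NULL))
    expect_equal(bray_curtis(counts), oracle_bray_curtis(counts))
  }

  zero <- rbind(a = c(1, 2), b = c(0, 0))
  expect_warning(bcz <- bray_curtis(zero), "all-zero")
  expect_true(is.na(bcz["a", "b"]))
  expect_error(bray_curtis(rbind(c(-1, 2))), "non-negative")
})
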