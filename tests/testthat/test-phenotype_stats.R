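test_that("TCR segment genes are stripped by prefix", {
  expect_equal(strip_tcr_genes(c("TRBV7-2", "CD8A", "TRAJ23")), "CD8A")
  expect_equal(strip_tcr_genes(c("IKZF2", "KIR2DL1")), c("IKZF2", "KIR2DL1"))
  expect_equal(strip_tcr_genes(character(0)), character(0))
  expect_equal(strip_tcr_genes(c("TRAC", "TRBC2", "TRBD1", "TRGC1")), "TRGC1")
})

test_that("log normalization matches the documented formula", {
  m <- matrix(c(0, 2, 8, 5, 0, 5, 1, 3, 6), nrow = 3,
              dimnames = list(c("g1", "g2", "g3"), c("c1", "c2", "c3")))
  norm <- as.matrix(normalize_cells(m, scale = 10))
  lib <- colSums(m)
  expected <- log1p(sweep(m, 2, lib, "/") * 10)
  expect_equal(norm, expected, tolerance = 1e-12)
  expect_equal(norm["g1", "c1"], 0)  # zero count stays zero
  # count equal to library size at scale = library size: ln(1 + lib)
  one <- matrix(4, 1, 1, dimnames = list("g", "c"))
  expect_equal(as.matrix(normalize_cells(one, scale = 4))[1, 1], log(1 + 4))
  zero <- matrix(0, 1, 1, dimnames = list("g", "empty"))
  expect_error(normalize_cells(zero), class = "clonoreact_validation_error")
  expect_error(normalize_cells(zero), "empty")
})

test_that("the 3-vs-3 rank-sum worked example gives exact p = 0.1", {
  m <- matrix(c(1, 2, 3, 10, 11, 12), nrow = 1,
              dimnames = list("g1", sprintf("c%d", 1:6)))
  res <- wilcoxon_de(m, labels = rep(c("A", "B"), each = 3), group1 = "A",
                     min_pct = 0)
  expect_equal(res$p_value, 0.1)
  # identical groups: p = 1, zero fold change
  m2 <- matrix(rep(c(1, 2, 3), 2), nrow = 1,
               dimnames = list("g1", sprintf("c%d", 1:6)))
  res2 <- wilcoxon_de(m2, labels = rep(c("A", "B"), each = 3), group1 = "A",
                      min_pct = 0)
  expect_equal(res2$p_value, 1)
  expect_equal(res2$avg_log2fc, 0)
})

test_that("exact rank-sum p agrees with brute-force enumeration", {
  set.seed(31)
  for (i in 1:15) {
    n1 <- sample(3:6, 1); n2 <- sample(3:6, 1)
    x <- rnorm(n1); y <- rnorm(n2, 1)
    p_pkg <- clonoreact:::rank_sum_p(c(x, y), seq_len(n1), n1 + seq_len(n2))
    expect_equal(p_pkg, oracle_rank_sum_p(x, y), tolerance = 1e-12)
  }
})

test_that("rank-sum p agrees with the standard two-sample Wilcoxon test", {
  set.seed(77)
  for (i in 1:10) {
    n1 <- sample(8:25, 1); n2 <- sample(8:25, 1)
    x <- rnorm(n1); y <- rnorm(n2, 0.5)
    p_pkg <- clonoreact:::rank_sum_p(c(x, y), seq_len(n1), n1 + seq_len(n2))
    expect_equal(p_pkg, stats::wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("normal-approximation p stays within 0.02 of exact enumeration", {
  set.seed(19)
  for (i in 1:10) {
    n1 <- sample(8:12, 1); n2 <- sample(8:12, 1)
    x <- rnorm(n1); y <- rnorm(n2, 0.8)
    approx_p <- clonoreact:::rank_sum_p(c(x, y), seq_len(n1), n1 + seq_len(n2),
                                        exact_max = 0)
    expect_lt(abs(approx_p - oracle_rank_sum_p(x, y)), 0.02)
  }
})

test_that("BH adjustment matches the brute-force step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.5, rep(1, 9))), oracle_bh(c(0.5, rep(1, 9))))
  set.seed(4)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
    # monotone along sorted raw p; clipped to [0, 1]
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
    expect_true(all(adj >= 0 & adj <= 1))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), class = "clonoreact_validation_error")
})

test_that("pseudobulk sums counts per sample and conserves total mass", {
  m <- matrix(c(3, 1, 7, 2, 5, 4), nrow = 1,
              dimnames = list("g", sprintf("c%d", 1:6)))
  pb <- pseudobulk(m, c("d1", "d2", "d1", "d2", "d3", "d3"))
  expect_equal(pb["g", "d1"], 10)  # cells with 3 and 7
  expect_equal(sum(pb), sum(m))
  # one cell per donor: pseudobulk equals the cell matrix
  pb1 <- pseudobulk(m, sprintf("d%d", 1:6))
  expect_equal(unname(pb1), unname(m))
  set.seed(12)
  big <- matrix(rpois(500, 3), nrow = 20,
                dimnames = list(sprintf("g%02d", 1:20), sprintf("c%02d", 1:25)))
  lab <- sample(c("s1", "s2", "s3"), 25, TRUE)
  pb2 <- pseudobulk(big, lab)
  for (s in unique(lab))
    expect_equal(unname(pb2[, s]), unname(rowSums(big[, lab == s, drop = FALSE])))
  expect_error(pseudobulk(big, c(lab[-1], NA)),
               class = "clonoreact_validation_error")
})

test_that("per-million normalization scales each sample column to 1e6", {
  pb <- matrix(c(5, 45, 10, 90), nrow = 2,
               dimnames = list(c("g1", "g2"), c("s1", "s2")))
  fpm <- fpm_normalize(pb)
  expect_equal(fpm["g1", "s1"], 1e5)  # count 5 in a total of 50
  expect_equal(unname(colSums(fpm)), c(1e6, 1e6), tolerance = 1e-6)
  # a sample already at 1e6 total is unchanged
  at_m <- matrix(c(4e5, 6e5), 2, 1, dimnames = list(c("g1", "g2"), "s"))
  expect_equal(fpm_normalize(at_m), at_m)
  zero <- matrix(0, 1, 1, dimnames = list("g", "s0"))
  expect_error(fpm_normalize(zero), class = "clonoreact_validation_error")
})

test_that("exact signed-rank enumeration matches its brute-force oracle", {
  # six uniformly signed pairs: only the two extreme assignments qualify
  expect_equal(exact_signed_rank(1:6, rep(0, 6)), 0.03125)
  # symmetric pair of differences
  expect_equal(exact_signed_rank(c(1, -1), c(0, 0)), 1.0)
  # two positive pairs: enumeration over the 4 assignments gives 0.5
  expect_equal(exact_signed_rank(c(1, 2), c(0, 0)),
               oracle_signed_rank_p(c(1, 2)))
  expect_equal(exact_signed_rank(c(1, 2), c(0, 0)), 0.5)
  set.seed(8)
  for (i in 1:10) {
    n <- sample(3:9, 1)
    a <- rnorm(n); b <- rnorm(n)
    expect_equal(exact_signed_rank(a, b), oracle_signed_rank_p(a - b),
                 tolerance = 1e-12)
  }
  expect_error(exact_signed_rank(c(1, 2), c(1, 2)),
               class = "clonoreact_undefined_test_error")
})

test_that("planted fold changes are recovered in a small DE run", {
  sim <- simulate_counts(n_genes = 300, n_de = 20, cells_per_group = 150,
                         seed = 21)
  norm <- normalize_cells(sim$counts)
  de <- wilcoxon_de(norm, sim$labels, group1 = "Ri_AIE")
  flagged <- de$gene[de$significant_up | de$significant_down]
  planted <- names(sim$truth)
  expect_gte(mean(planted %in% flagged), 0.7)
  # directions match the planted signs (group1 = second group of the sim)
  up <- de$gene[de$significant_up]
  expect_true(all(sim$truth[up[up %in% planted]] > 0))
})

test_that("label permutation yields near-uniform p-values", {
  sim <- simulate_counts(n_genes = 2000, n_de = 0, cells_per_group = 200,
                         seed = 5)
  norm <- normalize_cells(sim$counts)
  set.seed(5)
  labels <- sample(sim$labels)
  de <- wilcoxon_de(norm, labels, group1 = "AgD")
  ks <- suppressWarnings(stats::ks.test(de$p_value, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})
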