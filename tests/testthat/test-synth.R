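test_that("generators are pure functions of their parameters and seed", {
  a <- simulate_repertoire(n_clonotypes = 100, depth = 3000, seed = 7)
  b <- simulate_repertoire(n_clonotypes = 100, depth = 3000, seed = 7)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_false(identical(
    as.data.frame(simulate_repertoire(n_clonotypes = 100, depth = 3000, seed = 8)),
    as.data.frame(a)))
  cc1 <- simulate_coculture(a, n_reactive = 2, rare_min = 1e-4, rare_max = 1e-2,
                            seed = 3)
  cc2 <- simulate_coculture(a, n_reactive = 2, rare_min = 1e-4, rare_max = 1e-2,
                            seed = 3)
  expect_identical(cc1$truth, cc2$truth)
  expect_identical(as.data.frame(cc1$timecourse$day14),
                   as.data.frame(cc2$timecourse$day14))
  l1 <- simulate_luminescence(n_tcrs = 4, seed = 2)
  l2 <- simulate_luminescence(n_tcrs = 4, seed = 2)
  expect_identical(l1, l2)
  c1 <- simulate_counts(n_genes = 40, n_de = 2, cells_per_group = 10, seed = 9)
  c2 <- simulate_counts(n_genes = 40, n_de = 2, cells_per_group = 10, seed = 9)
  expect_identical(as.matrix(c1$counts), as.matrix(c2$counts))
  d1 <- simulate_cell_dataset(n_donors = c(AgD = 1), seed = 4)
  d2 <- simulate_cell_dataset(n_donors = c(AgD = 1), seed = 4)
  expect_identical(d1$cells, d2$cells)
})

test_that("generator parameters are validated", {
  expect_error(simulate_repertoire(alpha = 0), class = "clonoreact_parameter_error")
  base <- simulate_repertoire(n_clonotypes = 50, depth = 1000, seed = 1)
  expect_error(simulate_coculture(base, growth_factor = 1),
               class = "clonoreact_parameter_error")
  expect_error(simulate_coculture(base, n_reactive = 100),
               class = "clonoreact_parameter_error")
  expect_error(simulate_cell_dataset(n_clusters = 1),
               class = "clonoreact_parameter_error")
  expect_error(simulate_counts(dispersion = 0),
               class = "clonoreact_parameter_error")
})

test_that("simulated repertoires satisfy the sample invariants", {
  s <- simulate_repertoire(n_clonotypes = 500, depth = 2e4, seed = 13)
  expect_equal(sum(s$frequency), 1, tolerance = 1e-9)
  expect_equal(sum(s$count), attr(s, "total_count"))
  expect_false(anyDuplicated(s$cdr3b_aa) > 0)
  expect_true(all(grepl("^C[ACDEFGHIKLMNPQRSTVWY]+F$", s$cdr3b_aa)))
  # the underlying law is skewed: the top clone dominates the median clone
  expect_gt(s$frequency[1], 50 * median(s$frequency))
})

test_that("clonality grows with the power-law exponent in expectation", {
  mean_clonality <- function(alpha) {
    mean(vapply(1:15, function(seed) {
      s <- simulate_repertoire(n_clonotypes = 200, alpha = alpha, depth = 5000,
                               seed = seed)
      repertoire_summary(s)$clonality
    }, numeric(1)))
  }
  c_low <- mean_clonality(0.5)
  c_mid <- mean_clonality(1.5)
  c_high <- mean_clonality(2.5)
  expect_lt(c_low, c_mid)
  expect_lt(c_mid, c_high)
})

test_that("a unit growth factor leaves the timecourse null", {
  base <- simulate_repertoire(n_clonotypes = 500, depth = 5e4, seed = 17)
  cc <- simulate_coculture(base, growth_factor = 1.0001, seed = 17)
  calls <- call_expansions(cc$timecourse)
  # only multinomial noise: no clone at measurable ex vivo frequency expands
  measurable <- calls[calls$freq_exvivo_effective >= 1e-3, ]
  expect_equal(sum(measurable$expanded), 0)
})

test_that("cell datasets carry planted cluster residency and QC structure", {
  sim <- simulate_cell_dataset(seed = 99)
  cells <- sim$cells
  expect_false(anyDuplicated(cells$barcode) > 0)
  expect_true(all(cells$pct_mito >= 0 & cells$pct_mito <= 100))
  # planted clonotypes concentrate in the target cluster
  planted <- do.call(rbind, strsplit(sim$truth$target_cluster_clonotypes, ":"))
  for (i in seq_len(nrow(planted))) {
    sub <- cells[cells$donor_id == planted[i, 1] &
                   cells$cdr3b_aa == planted[i, 2], ]
    expect_gte(nrow(sub), 30)
    expect_gt(mean(sub$cluster_id == sim$truth$target_cluster), 0.6)
  }
  # with all QC-failure fractions at zero every cell passes the filter
  clean <- simulate_cell_dataset(n_donors = c(AgD = 1),
                                 qc_fail = c(multi_trb = 0, high_mito = 0,
                                             low_genes = 0), seed = 1)
  expect_equal(nrow(filter_cells(clean$cells)$removed), 0)
})

test_that("symmetric concentrations spread cells evenly across clusters", {
  sim <- simulate_cell_dataset(n_donors = c(AgD = 4), clonotypes_per_donor = 120,
                               planted_per_donor = 0, n_clusters = 4,
                               background_concentration = 50, seed = 6)
  tab <- table(sim$cells$cluster_id)
  expect_equal(length(tab), 4)
  expect_true(all(abs(tab / sum(tab) - 0.25) < 0.06))
})

test_that("contig tables are consistent with their cells", {
  sim <- simulate_cell_dataset(n_donors = c(AgD = 1), seed = 3)
  n_trb <- table(factor(sim$contigs$barcode[sim$contigs$chain == "TRB"],
                        levels = sim$cells$barcode))
  expect_equal(unname(as.integer(n_trb)), sim$cells$n_productive_trb)
})

test_that("planted counts scale the second group's means", {
  sim <- simulate_counts(n_genes = 200, n_de = 10, log2fc = 2,
                         cells_per_group = 400, seed = 44)
  m <- as.matrix(sim$counts)
  g2 <- sim$labels == "Ri_AIE"
  for (g in names(sim$truth)) {
    ratio <- mean(m[g, g2]) / mean(m[g, !g2])
    expect_equal(log2(ratio), sim$truth[[g]], tolerance = 0.5)
  }
})

test_that("a miniature study writes every pipeline input to disk", {
  outdir <- withr::local_tempdir()
  study <- simulate_study(outdir, seed = 5, depth = 2e4)
  expect_true(all(file.exists(unlist(study$paths[c(
    "exvivo", "day7", "day14", "cells", "contigs", "luminescence")]))))
  expect_true(file.exists(file.path(study$paths$counts, "matrix.mtx")))
  back <- read_airr_repertoire(study$paths$day14, timepoint = "day14")
  expect_equal(back$count, study$coculture$timecourse$day14$count)
  cells <- read_cell_metadata(study$paths$cells)
  expect_equal(nrow(cells), nrow(study$cells$cells))
})
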