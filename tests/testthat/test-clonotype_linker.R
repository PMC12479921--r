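make_cells <- function(n_trb, mito, genes, barcode = NULL) {
  data.frame(barcode = if (is.null(barcode)) sprintf("bc%03d", seq_along(n_trb))
             else barcode,
             pct_mito = mito, n_genes_detected = genes,
             n_productive_trb = n_trb, stringsAsFactors = FALSE)
}

test_that("cell QC applies the single-TRB, mito and gene rules in order", {
  cells <- make_cells(n_trb = c(1, 2, 1, 1, 0, 2),
                      mito = c(9.9, 5, 10.0, 12, 3, 40),
                      genes = c(150, 500, 99, 500, 500, 50))
  res <- filter_cells(cells)
  expect_equal(res$kept$barcode, "bc001")           # 1 TRB, 9.9%, 150 genes
  r <- setNames(res$removed$reason, res$removed$barcode)
  expect_equal(unname(r["bc002"]), "multiple TRB chains")
  # mito boundary 10.0 passes; this cell fails on genes instead
  expect_equal(unname(r["bc003"]), "too few genes")
  expect_equal(unname(r["bc004"]), "high mitochondrial fraction")
  expect_equal(unname(r["bc005"]), "no TRB chain")
  # first failing reason in fixed order: TRB before mito and genes
  expect_equal(unname(r["bc006"]), "multiple TRB chains")
  expect_equal(nrow(res$kept) + nrow(res$removed), nrow(cells))
})

test_that("cell QC partitions any random fixture and validates its inputs", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- 200
    cells <- make_cells(n_trb = sample(0:3, n, TRUE, prob = c(.1, .7, .15, .05)),
                        mito = runif(n, 0, 20), genes = sample(10:2000, n, TRUE))
    res <- filter_cells(cells)
    expect_equal(nrow(res$kept) + nrow(res$removed), n)
    expect_true(all(res$kept$n_productive_trb == 1))
    expect_true(all(res$kept$pct_mito <= 10))
    expect_true(all(res$kept$n_genes_detected >= 100))
  }
  bad <- make_cells(1, NA, 500)
  expect_error(filter_cells(bad), class = "clonoreact_validation_error")
  expect_error(filter_cells(bad), "bc001")
})

test_that("gene filter keeps genes expressed in at least min_cells cells", {
  m <- rbind(ten = c(rep(1, 10), rep(0, 10)),
             nine = c(rep(1, 9), rep(0, 11)),
             zero = rep(0, 20))
  colnames(m) <- sprintf("c%02d", 1:20)
  kept <- filter_genes(m, min_cells = 10)
  expect_equal(rownames(kept), "ten")
  expect_equal(ncol(kept), 20)
  expect_warning(filter_genes(m[3, , drop = FALSE]), "no gene")
})

test_that("mitochondrial percentage is computed from MT- prefixed genes", {
  m <- rbind(`MT-CO1` = c(5, 0), `MT-ND1` = c(5, 0), ACTB = c(90, 10))
  colnames(m) <- c("a", "b")
  expect_equal(pct_mito_from_counts(m), c(a = 10, b = 0))
})

test_that("cluster profiles tally cells per clonotype and flag expansion", {
  cells <- data.frame(
    donor_id = "Ri01", group = "Ri_AIE",
    cdr3b_aa = c(rep("CASSHEAD", 46), "CASSLONE", "CASSPAIR", "CASSPAIR"),
    cluster_id = c(rep(1, 43), 2, 2, 3, 8, 5, 5),
    stringsAsFactors = FALSE)
  prof <- build_cluster_profiles(cells)
  head_rows <- prof[prof$cdr3b_aa == "CASSHEAD", ]
  expect_equal(unique(head_rows$total_cells), 46)
  expect_equal(head_rows$fraction[head_rows$cluster_id == 1], 43 / 46,
               tolerance = 1e-9)
  expect_equal(round(100 * head_rows$fraction[head_rows$cluster_id == 1], 2),
               93.48)
  expect_true(all(head_rows$exvivo_expanded))
  expect_false(prof$exvivo_expanded[prof$cdr3b_aa == "CASSLONE"])
  pair <- prof[prof$cdr3b_aa == "CASSPAIR", ]
  expect_equal(pair$fraction, 1.0)
  expect_true(pair$exvivo_expanded)
  # per-clonotype fractions always sum to one
  sums <- tapply(prof$fraction, paste(prof$donor_id, prof$cdr3b_aa), sum)
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("profiles drop unlabeled cells and conserve the labeled total", {
  cells <- data.frame(donor_id = "d", group = "AgD",
                      cdr3b_aa = c("CASSA", "CASSA", NA, "CASSB"),
                      cluster_id = c(1, NA, 2, 2), stringsAsFactors = FALSE)
  expect_message(prof <- build_cluster_profiles(cells), "2 cell")
  expect_equal(sum(prof$n_cells), 2)
})

test_that("candidate selection applies the >=10-cell and >60% rules", {
  prof <- data.frame(
    donor_id = "d", group = "AgD",
    cdr3b_aa = rep(c("CASSPASS", "CASSFEW", "CASSHALF"), times = c(2, 1, 2)),
    cluster_id = c(1, 2, 1, 1, 2),
    n_cells = c(15, 5, 9, 50, 50),
    total_cells = c(20, 20, 9, 100, 100),
    fraction = c(0.75, 0.25, 1, 0.5, 0.5),
    exvivo_expanded = TRUE, stringsAsFactors = FALSE)
  sel <- select_candidates(prof, target_cluster = 1)
  s <- setNames(sel$selected, sel$cdr3b_aa)
  expect_true(s[["CASSPASS"]])    # 15 of 20 (75%)
  expect_false(s[["CASSFEW"]])    # 9 cells at 100%: fails >=10
  expect_false(s[["CASSHALF"]])   # 50 of 100: fails >60%
  expect_equal(sel$cdr3b_aa[1], "CASSHALF")  # sorted by target-cluster cells
  expect_warning(select_candidates(prof, target_cluster = 99), "absent")
})

test_that("raising the selection thresholds never adds a candidate", {
  set.seed(42)
  cells <- simulate_cell_dataset(n_donors = c(AgD = 2), seed = 42)$cells
  prof <- build_cluster_profiles(filter_cells(cells)$kept)
  base <- select_candidates(prof, target_cluster = 1)
  stricter_n <- select_candidates(prof, target_cluster = 1, min_cells = 15)
  stricter_f <- select_candidates(prof, target_cluster = 1, min_fraction = 0.8)
  key <- function(d) d$cdr3b_aa[d$selected]
  expect_true(all(key(stricter_n) %in% key(base)))
  expect_true(all(key(stricter_f) %in% key(base)))
})

test_that("cohort statistics aggregate counts, means and percentages", {
  # two groups, known composition: 3 clonotypes / 2 donors and 2 / 1 donor
  prof <- data.frame(
    donor_id = c("a1", "a1", "a2", "b1", "b1"),
    group = c("AgD", "AgD", "AgD", "Ri_AIE", "Ri_AIE"),
    cdr3b_aa = c("CASSA", "CASSB", "CASSC", "CASSD", "CASSE"),
    cluster_id = 1,
    n_cells = c(10, 1, 4, 20, 2),
    total_cells = c(10, 1, 4, 20, 2),
    fraction = 1,
    exvivo_expanded = c(TRUE, FALSE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE)
  stats <- cohort_cluster_stats(prof, target_cluster = 1)
  agd <- stats[stats$group == "AgD", ]
  expect_equal(agd$n_clonotypes, 3)
  expect_equal(agd$n_cells, 15)
  expect_equal(agd$mean_clonotypes_per_donor, 1.5)
  expect_equal(agd$pct_expanded_clonotypes, 66.7)
  expect_equal(agd$pct_cells_from_expanded, 93.3)  # 14 of 15 cells
  pooled <- stats[stats$group == "pooled", ]
  expect_equal(pooled$n_clonotypes, 5)
  expect_equal(pooled$n_cells, 37)
})

test_that("VDJ mapping-rate means are unweighted over samples", {
  rates <- data.frame(sample_id = c("s1", "s2", "s1", "s2"),
                      chain = c("TRB", "TRB", "TRA", "TRA"),
                      pct_mapped = c(97, 98, 60, 70))
  res <- vdj_mapping_rates(rates)
  expect_equal(res$cohort_mean$mean_pct_mapped[res$cohort_mean$chain == "TRB"],
               97.50)
  expect_equal(res$cohort_mean$mean_pct_mapped[res$cohort_mean$chain == "TRA"],
               65.00)
  single <- vdj_mapping_rates(data.frame(sample_id = "s", chain = "TRB",
                                         pct_mapped = 50))
  expect_equal(single$cohort_mean$mean_pct_mapped, 50.00)
  expect_error(vdj_mapping_rates(NULL), class = "clonoreact_validation_error")
})
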