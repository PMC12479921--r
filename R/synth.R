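# Synthetic-data generators with planted ground truth. Defaults emulate the
# study conditions every stage assumes: skewed clone-size distributions with
# a minority of rare clones expanding over a 14-day coculture under
# multinomial sequencing sampling; clonotype-labeled cells whose cluster
# membership is concentrated in one cluster for a planted subset; negative
# binomial counts with planted group fold changes; lognormal reporter
# signals for reactive vs non-reactive TCRs.

random_cdr3 <- function(n, min_len = 10, max_len = 20) {
  lens <- sample(min_len:max_len, n, replace = TRUE)
  out <- vapply(lens, function(l)
    paste0("C", paste(sample(AA_ALPHABET, l - 2, replace = TRUE), collapse = ""), "F"),
    character(1))
  while (anyDuplicated(out)) {
    dup <- which(duplicated(out))
    out[dup] <- vapply(lens[dup], function(l)
      paste0("C", paste(sample(AA_ALPHABET, l - 2, replace = TRUE), collapse = ""), "F"),
      character(1))
  }
  out
}

rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  x / sum(x)
}

#' Simulate a bulk TCR-beta repertoire
#'
#' Clone probabilities follow a discrete power law on ranks
#' (p_i proportional to i^-alpha), reproducing the few-large-clones,
#' long-rare-tail shape of real CD8+ repertoires; sequencing counts are
#' drawn multinomially at the given depth. CDR3-beta strings are random
#' unique amino-acid sequences (C...F, length 10-20).
#'
#' @param n_clonotypes Number of clones in the underlying repertoire.
#' @param alpha Power-law exponent (> 0; default 2).
#' @param depth Sequencing depth (total productive reads).
#' @param seed Integer seed.
#' @param sample_id,donor_id,timepoint Metadata for the sample.
#' @param input_cell_count Input CD8+ cell number (default `depth`).
#' @return A [repertoire_sample()] of the clones observed at least once;
#'   the full probability vector is attached as attribute `true_probs`
#'   (named by CDR3b).
#' @export
simulate_repertoire <- function(n_clonotypes = 2000, alpha = 2, depth = 1e5,
                                seed = 1, sample_id = "sim_exvivo",
                                donor_id = "simdonor", timepoint = "ex_vivo",
                                input_cell_count = depth) {
  if (alpha <= 0)
    abort_clonoreact("power-law exponent alpha must be > 0", "clonoreact_parameter_error")
  stopifnot(n_clonotypes >= 2, depth >= n_clonotypes)
  with_substream(seed, "repertoire", {
    probs <- (seq_len(n_clonotypes))^(-alpha)
    probs <- probs / sum(probs)
    cdr3 <- random_cdr3(n_clonotypes)
    counts <- as.integer(stats::rmultinom(1, size = depth, prob = probs))
    observed <- counts > 0
    s <- repertoire_sample(sample_id, donor_id, timepoint,
                           data.frame(cdr3b_aa = cdr3[observed],
                                      count = counts[observed],
                                      stringsAsFactors = FALSE),
                           input_cell_count = input_cell_count)
    attr(s, "true_probs") <- stats::setNames(probs, cdr3)
    s
  })
}

#' Simulate a PBMC-neuron coculture timecourse
#'
#' Starting from a base ex vivo repertoire, a set of rare reactive clones
#' (ex vivo frequency below `rare_max`) grows by `growth_factor` per 7-day
#' interval; probabilities are renormalized and counts resampled
#' multinomially at each timepoint, so the day-14 expected fold is roughly
#' the squared weekly growth under deep sampling.
#'
#' @param base A [repertoire_sample()] (the ex vivo sample); its
#'   `true_probs` attribute is used when present, else its observed
#'   frequencies.
#' @param n_reactive Number of reactive clones to plant (default 6).
#' @param growth_factor Weekly growth multiplier (> 1; default 20).
#' @param rare_min,rare_max Eligibility window on the ex vivo frequency of
#'   reactive precursors (defaults 2e-5 and 1e-4): rare clones, below the
#'   0.01% detection-scale ceiling, yet abundant enough that two weekly
#'   growth rounds carry them past the 0.5% day-14 reporting floor.
#' @param depth Sequencing depth per timepoint (default: the base total).
#' @param seed Integer seed.
#' @return List with `timecourse` (a [timecourse_repertoire()]) and `truth`
#'   (seed, planted `reactive_clonotypes`, `growth_factor_per_week`).
#' @export
simulate_coculture <- function(base, n_reactive = 6, growth_factor = 20,
                               rare_min = 2e-5, rare_max = 1e-4,
                               depth = NULL, seed = 1) {
  stopifnot(inherits(base, "repertoire_sample"))
  if (growth_factor <= 1)
    abort_clonoreact("growth_factor must exceed 1", "clonoreact_parameter_error")
  probs <- attr(base, "true_probs")
  if (is.null(probs)) probs <- stats::setNames(base$frequency, base$cdr3b_aa)
  if (is.null(depth)) depth <- attr(base, "total_count")
  eligible <- names(probs)[probs < rare_max & probs >= rare_min]
  if (length(eligible) < n_reactive)
    abort_clonoreact(sprintf(
      "only %d clones in the rare-precursor window [%g, %g); simulate a larger repertoire",
      length(eligible), rare_min, rare_max), "clonoreact_parameter_error")
  with_substream(seed, "coculture", {
    reactive <- sample(eligible, n_reactive)
    donor <- attr(base, "donor_id")
    grow <- function(p) {
      p[reactive] <- p[reactive] * growth_factor
      p / sum(p)
    }
    draw <- function(p, tp, id) {
      counts <- as.integer(stats::rmultinom(1, size = depth, prob = p))
      keep <- counts > 0
      repertoire_sample(id, donor, tp,
                        data.frame(cdr3b_aa = names(p)[keep], count = counts[keep],
                                   stringsAsFactors = FALSE),
                        input_cell_count = attr(base, "input_cell_count"))
    }
    p7 <- grow(probs)
    p14 <- grow(p7)
    tc <- timecourse_repertoire(base,
                                draw(p7, "day7", paste0(donor, "_day7")),
                                draw(p14, "day14", paste0(donor, "_day14")))
    list(timecourse = tc,
         truth = list(seed = seed, reactive_clonotypes = reactive,
                      growth_factor_per_week = growth_factor))
  })
}

#' Simulate a clonotype-labeled single-cell dataset
#'
#' Cells carry donor, group, QC fields, a CDR3-beta clonotype label and a
#' cluster assignment. Cluster memberships per clonotype are
#' Dirichlet-multinomial: planted target-cluster-resident clonotypes use a
#' concentration vector putting `planted_target_mass` expected mass on the
#' target cluster, background clonotypes a symmetric concentration. QC
#' fields are drawn so a configured fraction of cells fails each filter.
#'
#' @param n_donors Named vector, donors per group (default `c(AgD = 3,
#'   Ri_AIE = 7)`).
#' @param clonotypes_per_donor Background clonotypes per donor (default 40).
#' @param planted_per_donor Planted target-resident clonotypes per donor
#'   (default 3).
#' @param planted_cells Range of cells for planted clonotypes (default
#'   30-60).
#' @param p_singleton Geometric parameter of background clonotype sizes
#'   (default 0.58: about 42% of clonotypes are seen in >= 2 cells, as in
#'   effector-enriched clusters).
#' @param n_clusters,target_cluster Cluster structure (defaults 16 and 1).
#' @param planted_target_mass Expected target-cluster mass of planted
#'   clonotypes (default 0.93, matching the strongly resident clonotypes
#'   the pipeline is meant to find).
#' @param concentration_total Dirichlet concentration mass for planted
#'   clonotypes (default 150; larger = tighter around the expected mass).
#' @param background_concentration Symmetric per-cluster concentration of
#'   background clonotypes (default 2).
#' @param qc_fail Named fractions of cells failing each QC filter:
#'   `multi_trb`, `high_mito`, `low_genes`.
#' @param seed Integer seed.
#' @return List with `cells` (data frame, one row per cell: `barcode`,
#'   `donor_id`, `group`, `sample_tag`, `n_genes_detected`, `pct_mito`,
#'   `n_productive_trb`, `n_productive_tra`, `cdr3b_aa`, `cluster_id`),
#'   `contigs` (a 10x-style contig annotation table for the same cells)
#'   and `truth` (planted `target_cluster_clonotypes` as donor-scoped
#'   "donor:cdr3" keys, plus parameters).
#' @export
simulate_cell_dataset <- function(n_donors = c(AgD = 3, Ri_AIE = 7),
                                  clonotypes_per_donor = 40,
                                  planted_per_donor = 3,
                                  planted_cells = c(30, 60),
                                  p_singleton = 0.58,
                                  n_clusters = 16, target_cluster = 1,
                                  planted_target_mass = 0.93,
                                  concentration_total = 150,
                                  background_concentration = 2,
                                  qc_fail = c(multi_trb = 0.05,
                                              high_mito = 0.05,
                                              low_genes = 0.03),
                                  seed = 1) {
  if (n_clusters < 2)
    abort_clonoreact("at least 2 clusters required", "clonoreact_parameter_error")
  clusters <- seq_len(n_clusters) - 1L
  if (!target_cluster %in% clusters)
    abort_clonoreact("target_cluster outside 0..(n_clusters-1)",
                     "clonoreact_parameter_error")
  alpha_planted <- rep(concentration_total * (1 - planted_target_mass) /
                         (n_clusters - 1), n_clusters)
  alpha_planted[target_cluster + 1] <- concentration_total * planted_target_mass
  alpha_bg <- rep(background_concentration, n_clusters)
  with_substream(seed, "cell_dataset", {
    rows <- list(); planted_keys <- character(0)
    for (g in names(n_donors)) for (d in seq_len(n_donors[[g]])) {
      donor <- sprintf("%s%02d", g, d)
      n_bg <- clonotypes_per_donor
      cdr3 <- random_cdr3(n_bg + planted_per_donor)
      planted <- seq_len(planted_per_donor)
      planted_keys <- c(planted_keys, paste(donor, cdr3[planted], sep = ":"))
      sizes <- c(sample(planted_cells[1]:planted_cells[2], planted_per_donor,
                        replace = TRUE),
                 1 + stats::rgeom(n_bg, p_singleton))
      for (k in seq_along(cdr3)) {
        alpha <- if (k %in% planted) alpha_planted else alpha_bg
        p <- rdirichlet1(alpha)
        cl <- sample(clusters, sizes[k], replace = TRUE, prob = p)
        rows[[length(rows) + 1]] <- data.frame(
          donor_id = donor, group = g, cdr3b_aa = cdr3[k], cluster_id = cl,
          stringsAsFactors = FALSE)
      }
    }
    cells <- do.call(rbind, rows)
    n <- nrow(cells)
    cells$barcode <- sprintf("%s-%06d", cells$donor_id, seq_len(n))
    cells$sample_tag <- paste0(cells$donor_id, "_exvivo")
    # QC fields: draw passing values, then knock out configured fractions
    cells$n_productive_trb <- 1L
    cells$n_productive_tra <- sample(0:2, n, replace = TRUE,
                                     prob = c(0.35, 0.55, 0.10))
    cells$pct_mito <- stats::runif(n, 0, 9.5)
    cells$n_genes_detected <- as.integer(stats::runif(n, 500, 4000))
    fail_trb <- stats::runif(n) < qc_fail[["multi_trb"]]
    cells$n_productive_trb[fail_trb] <- 2L
    fail_mito <- stats::runif(n) < qc_fail[["high_mito"]]
    cells$pct_mito[fail_mito] <- stats::runif(sum(fail_mito), 10.5, 60)
    fail_genes <- stats::runif(n) < qc_fail[["low_genes"]]
    cells$n_genes_detected[fail_genes] <-
      as.integer(stats::runif(sum(fail_genes), 5, 99))
    cells <- cells[, c("barcode", "donor_id", "group", "sample_tag",
                       "n_genes_detected", "pct_mito", "n_productive_trb",
                       "n_productive_tra", "cdr3b_aa", "cluster_id")]
    rownames(cells) <- NULL
    contigs <- simulate_contigs(cells)
    list(cells = cells, contigs = contigs,
         truth = list(seed = seed,
                      target_cluster_clonotypes = planted_keys,
                      target_cluster = target_cluster,
                      planted_target_mass = planted_target_mass,
                      qc_fail = qc_fail))
  })
}

# One 10x-style contig row per productive chain of each cell.
simulate_contigs <- function(cells) {
  per_cell <- lapply(seq_len(nrow(cells)), function(i) {
    n_trb <- cells$n_productive_trb[i]
    n_tra <- cells$n_productive_tra[i]
    trb_cdr3 <- if (n_trb >= 1)
      c(cells$cdr3b_aa[i],
        if (n_trb > 1) random_cdr3(n_trb - 1)) else character(0)
    tra_cdr3 <- if (n_tra >= 1) random_cdr3(n_tra) else character(0)
    data.frame(barcode = cells$barcode[i],
               chain = c(rep("TRB", n_trb), rep("TRA", n_tra)),
               cdr3 = c(trb_cdr3, tra_cdr3),
               productive = "TRUE", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, per_cell)
  rownames(out) <- NULL
  out
}

#' Simulate a gene-by-cell counts matrix with planted fold changes
#'
#' Counts are negative binomial around lognormal gene means; for planted
#' genes the second group's mean is scaled by 2^log2FC. Library sizes
#' emerge from the draws. Gene means emulate the moderately-to-highly
#' expressed genes on which cell-level testing is powered (the min_pct
#' expression filter discards the near-zero tail of a real transcriptome
#' anyway).
#'
#' @param n_genes Number of genes (default 2000).
#' @param planted_log2fc Named numeric vector gene index -> log2FC, or a
#'   count `n_de` split half up / half down at `|log2fc|`.
#' @param n_de,log2fc Used when `planted_log2fc` is NULL: plant `n_de`
#'   genes (default 100), half at +`log2fc`, half at -`log2fc` (default 1).
#' @param cells_per_group Cells in each of the two groups (default 500).
#' @param mean_log,mean_sdlog Lognormal parameters of gene means (defaults
#'   log(2) and 0.8).
#' @param dispersion Negative binomial dispersion (default 0.5; variance =
#'   mu + dispersion * mu^2).
#' @param groups Group labels (default `c("AgD", "Ri_AIE")`; fold changes
#'   are group2 over group1).
#' @param seed Integer seed.
#' @return List with `counts` (sparse dgCMatrix, genes x cells), `labels`
#'   (group per cell) and `truth` (named log2FC vector over planted genes).
#' @export
simulate_counts <- function(n_genes = 2000, planted_log2fc = NULL, n_de = 100,
                            log2fc = 1, cells_per_group = 500,
                            mean_log = log(2), mean_sdlog = 0.8,
                            dispersion = 0.5, groups = c("AgD", "Ri_AIE"),
                            seed = 1) {
  if (dispersion <= 0)
    abort_clonoreact("dispersion must be positive", "clonoreact_parameter_error")
  with_substream(seed, "counts", {
    genes <- sprintf("GENE%05d", seq_len(n_genes))
    if (is.null(planted_log2fc)) {
      idx <- sample(n_genes, n_de)
      planted_log2fc <- stats::setNames(
        rep(c(log2fc, -log2fc), length.out = n_de), genes[idx])
    }
    mu <- stats::rlnorm(n_genes, mean_log, mean_sdlog)
    if (any(!is.finite(mu)))
      abort_clonoreact("non-finite gene mean drawn", "clonoreact_parameter_error")
    names(mu) <- genes
    mu2 <- mu
    mu2[names(planted_log2fc)] <- mu[names(planted_log2fc)] *
      2^unname(planted_log2fc)
    size <- 1 / dispersion
    n1 <- cells_per_group; n2 <- cells_per_group
    draw_group <- function(mu_g, n_cells)
      matrix(stats::rnbinom(n_genes * n_cells, mu = rep(mu_g, n_cells),
                            size = size), nrow = n_genes)
    m <- cbind(draw_group(mu, n1), draw_group(mu2, n2))
    dimnames(m) <- list(genes,
                        c(sprintf("%s-%04d", groups[1], seq_len(n1)),
                          sprintf("%s-%04d", groups[2], seq_len(n2))))
    labels <- rep(groups, c(n1, n2))
    list(counts = methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix"),
         labels = labels, truth = planted_log2fc)
  })
}

#' Simulate NFAT-reporter luminescence readouts
#'
#' Reactive TCRs emit a strong lognormal signal against stimulated neurons
#' (median ~20000 RLU above background) that collapses to background under
#' HLA blockade; non-reactive TCRs stay at background everywhere. A
#' configurable fraction of reactive TCRs also responds to PBMCs at lower
#' intensity. Mock and TransAct control wells are included; every
#' condition is run in duplicate.
#'
#' @param n_tcrs Named vector of TCRs per group (default `c(AgD = 27,
#'   Ri_AIE = 21)`) or a single count.
#' @param reactive_fraction Fraction of TCRs planted reactive (default
#'   0.42).
#' @param pbmc_cross_fraction Fraction of reactive TCRs also PBMC-positive
#'   (default 0.85).
#' @param mock_median,stim_median,pbmc_median,transact_median Medians (RLU)
#'   of the mock background and the adjusted stimulated-neuron, PBMC and
#'   TransAct signals.
#' @param noise_sdlog Lognormal replicate noise (default 0.25).
#' @param replicates Replicates per condition (default 2).
#' @param seed Integer seed.
#' @return List with `assays` (the [read_luminescence()] structure) and
#'   `truth` (`reactive_tcrs`, `pbmc_positive_tcrs`).
#' @export
simulate_luminescence <- function(n_tcrs = c(AgD = 27, Ri_AIE = 21),
                                  reactive_fraction = 0.42,
                                  pbmc_cross_fraction = 0.85,
                                  mock_median = 1000, stim_median = 20000,
                                  pbmc_median = 9000, transact_median = 80000,
                                  noise_sdlog = 0.25, replicates = 2,
                                  seed = 1) {
  stopifnot(reactive_fraction >= 0, reactive_fraction <= 1)
  if (is.null(names(n_tcrs))) n_tcrs <- c(cohort = n_tcrs)
  with_substream(seed, "luminescence", {
    assays <- list(); reactive_ids <- character(0); pbmc_ids <- character(0)
    lnorm <- function(median, n) median * exp(stats::rnorm(n, 0, noise_sdlog))
    for (g in names(n_tcrs)) for (i in seq_len(n_tcrs[[g]])) {
      id <- sprintf("%s_TCR%03d", g, i)
      reactive <- stats::runif(1) < reactive_fraction
      crossing <- reactive && stats::runif(1) < pbmc_cross_fraction
      if (reactive) reactive_ids <- c(reactive_ids, id)
      if (crossing) pbmc_ids <- c(pbmc_ids, id)
      bg <- function() lnorm(mock_median, replicates)
      reps <- list(
        mock = bg(),
        transact = bg() + lnorm(transact_median, replicates),
        neurons_unstim = bg(),
        neurons_stim = if (reactive) bg() + lnorm(stim_median, replicates) else bg(),
        neurons_stim_hla_block = bg(),
        pbmc = if (crossing) bg() + lnorm(pbmc_median, replicates) else bg())
      assays[[id]] <- list(tcr_id = id, donor_id = paste0(g, "01"), group = g,
                           replicates = reps)
    }
    list(assays = assays,
         truth = list(seed = seed, reactive_tcrs = reactive_ids,
                      pbmc_positive_tcrs = pbmc_ids))
  })
}

#' Generate a complete miniature study on disk
#'
#' One call produces every input the pipeline reads: an ex vivo / day-7 /
#' day-14 coculture timecourse as AIRR rearrangement TSVs, a
#' clonotype-labeled cell dataset (metadata TSV + 10x-style contig CSV),
#' a counts matrix with planted fold changes (Matrix Market triplet), a
#' luminescence plate CSV, and a manifest recording parameters and truth.
#'
#' @param outdir Output directory (created).
#' @param seed Integer seed; all generators derive independent substreams
#'   from it.
#' @param depth Bulk sequencing depth (default 1e5).
#' @return Invisibly, a list with all generated objects, their truth
#'   records and the file paths written.
#' @export
simulate_study <- function(outdir, seed = 1, depth = 1e5) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  base <- simulate_repertoire(n_clonotypes = 2000, depth = depth, seed = seed,
                              sample_id = "Ri01_exvivo", donor_id = "Ri01")
  cc <- simulate_coculture(base, seed = seed)
  cellset <- simulate_cell_dataset(seed = seed)
  cnt <- simulate_counts(seed = seed)
  lum <- simulate_luminescence(seed = seed)
  paths <- list(
    exvivo = file.path(outdir, "bulk_exvivo.tsv"),
    day7 = file.path(outdir, "bulk_day7.tsv"),
    day14 = file.path(outdir, "bulk_day14.tsv"),
    cells = file.path(outdir, "cell_metadata.tsv"),
    contigs = file.path(outdir, "filtered_contig_annotations.csv"),
    counts = file.path(outdir, "counts"),
    luminescence = file.path(outdir, "luminescence.csv"),
    manifest = file.path(outdir, "manifest.json"))
  write_airr_repertoire(cc$timecourse$ex_vivo, paths$exvivo)
  write_airr_repertoire(cc$timecourse$day7, paths$day7)
  write_airr_repertoire(cc$timecourse$day14, paths$day14)
  utils::write.table(cellset$cells, paths$cells, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.csv(cellset$contigs, paths$contigs, row.names = FALSE,
                   quote = FALSE)
  write_counts_mtx(cnt$counts, paths$counts)
  write_luminescence(lum$assays, paths$luminescence)
  manifest <- list(seed = seed, depth = depth,
                   truth = list(coculture = cc$truth, cells = cellset$truth,
                                counts = list(planted_log2fc = as.list(cnt$truth)),
                                luminescence = lum$truth))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE, digits = NA)
  } else {
    dput(manifest, file = sub("json$", "R", paths$manifest))
    paths$manifest <- sub("json$", "R", paths$manifest)
  }
  invisible(list(coculture = cc, cells = cellset, counts = cnt,
                 luminescence = lum, paths = paths))
}
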