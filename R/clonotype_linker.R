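# Single-cell QC, clonotype/cluster linkage and candidate selection.

#' Single-cell quality filter
#'
#' Keeps cells with exactly one productive TRB chain (when required), at
#' most `max_pct_mito` percent mitochondrial reads and at least `min_genes`
#' genes detected. Removed cells carry the first failing reason, checked in
#' the fixed order TRB chain, mitochondrial fraction, gene count.
#'
#' @param cells Data frame with columns `barcode`, `pct_mito`,
#'   `n_genes_detected`, `n_productive_trb` (plus any annotation columns,
#'   which are carried through).
#' @param max_pct_mito Maximum mitochondrial percentage (default 10; the
#'   boundary value passes).
#' @param min_genes Minimum genes detected (default 100; boundary passes).
#' @param require_single_trb Require exactly one productive TRB (default TRUE).
#' @return List with `kept` (data frame) and `removed` (data frame with an
#'   added `reason` column). `nrow(kept) + nrow(removed) == nrow(cells)`.
#' @export
filter_cells <- function(cells, max_pct_mito = 10, min_genes = 100,
                         require_single_trb = TRUE) {
  required <- c("barcode", "pct_mito", "n_genes_detected", "n_productive_trb")
  for (col in required) {
    if (is.null(cells[[col]]))
      abort_clonoreact(sprintf("cells lack QC column '%s'", col),
                       "clonoreact_validation_error")
    bad <- which(is.na(cells[[col]]))
    if (length(bad) > 0)
      abort_clonoreact(sprintf("missing %s for barcode %s", col,
                               cells$barcode[bad[1]]),
                       "clonoreact_validation_error")
  }
  reason <- rep(NA_character_, nrow(cells))
  if (require_single_trb)
    reason[cells$n_productive_trb != 1] <-
      ifelse(cells$n_productive_trb[cells$n_productive_trb != 1] > 1,
             "multiple TRB chains", "no TRB chain")
  sel <- is.na(reason) & cells$pct_mito > max_pct_mito
  reason[sel] <- "high mitochondrial fraction"
  sel <- is.na(reason) & cells$n_genes_detected < min_genes
  reason[sel] <- "too few genes"
  kept <- cells[is.na(reason), , drop = FALSE]
  removed <- cells[!is.na(reason), , drop = FALSE]
  removed$reason <- reason[!is.na(reason)]
  rownames(kept) <- rownames(removed) <- NULL
  list(kept = kept, removed = removed)
}

#' Gene presence filter
#'
#' Retains genes expressed (nonzero) in at least `min_cells` cells. Applied
#' after the cell filter, so presence is counted over kept cells only.
#'
#' @param m Gene-by-cell counts matrix (sparse or dense).
#' @param min_cells Minimum number of expressing cells (default 10;
#'   boundary passes).
#' @return The matrix restricted to retained genes; cell set unchanged.
#' @export
filter_genes <- function(m, min_cells = 10) {
  n_expressing <- Matrix::rowSums(m > 0)
  keep <- n_expressing >= min_cells
  if (!any(keep)) warning("no gene is expressed in enough cells")
  m[keep, , drop = FALSE]
}

#' Percent mitochondrial reads per cell
#'
#' Computed from the counts matrix when not supplied upstream: 100 x
#' (counts of genes whose identifier starts with `prefix`) / library size.
#'
#' @param m Gene-by-cell counts matrix with gene rownames.
#' @param prefix Mitochondrial gene prefix (default `"MT-"`).
#' @return Numeric vector, one percentage per cell (0 for empty cells).
#' @export
pct_mito_from_counts <- function(m, prefix = "MT-") {
  lib <- Matrix::colSums(m)
  mito <- Matrix::colSums(m[startsWith(rownames(m), prefix), , drop = FALSE])
  ifelse(lib > 0, 100 * mito / lib, 0)
}

#' Per-clonotype cluster composition profiles
#'
#' Clonotypes are defined by identical CDR3-beta amino-acid sequence within
#' a donor. For each (donor, CDR3b) the cells are tallied per expression
#' cluster; a clonotype seen in >= 2 cells is flagged as expanded ex vivo.
#' Cells lacking a clonotype or a cluster label are excluded (with a
#' message when any are dropped).
#'
#' @param cells Kept cells with columns `donor_id`, `group`, `cdr3b_aa`,
#'   `cluster_id`.
#' @return Data frame, one row per (donor, clonotype, cluster):
#'   `donor_id`, `group`, `cdr3b_aa`, `cluster_id`, `n_cells`,
#'   `total_cells`, `fraction`, `exvivo_expanded`.
#' @export
build_cluster_profiles <- function(cells) {
  usable <- !is.na(cells$cdr3b_aa) & nzchar(cells$cdr3b_aa) & !is.na(cells$cluster_id)
  n_dropped <- sum(!usable)
  if (n_dropped > 0)
    message(sprintf("excluding %d cell(s) lacking a clonotype or cluster label",
                    n_dropped))
  cells <- cells[usable, , drop = FALSE]
  if (nrow(cells) == 0)
    return(data.frame(donor_id = character(), group = character(),
                      cdr3b_aa = character(), cluster_id = integer(),
                      n_cells = integer(), total_cells = integer(),
                      fraction = numeric(), exvivo_expanded = logical()))
  key <- interaction(cells$donor_id, cells$cdr3b_aa, cells$cluster_id, drop = TRUE)
  agg <- stats::aggregate(list(n_cells = rep(1L, nrow(cells))),
                          by = list(donor_id = cells$donor_id,
                                    group = cells$group,
                                    cdr3b_aa = cells$cdr3b_aa,
                                    cluster_id = cells$cluster_id), FUN = sum)
  clone_key <- paste(agg$donor_id, agg$cdr3b_aa, sep = "\r")
  totals <- tapply(agg$n_cells, clone_key, sum)
  agg$total_cells <- as.integer(totals[clone_key])
  agg$fraction <- agg$n_cells / agg$total_cells
  agg$exvivo_expanded <- agg$total_cells >= 2
  agg <- agg[order(agg$donor_id, agg$cdr3b_aa, agg$cluster_id), ]
  rownames(agg) <- NULL
  agg
}

#' Select candidate clonotypes by target-cluster residency
#'
#' A clonotype is selected when it has at least `min_cells` cells in the
#' target cluster and strictly more than `min_fraction` of its cells reside
#' there.
#'
#' @param profiles Output of [build_cluster_profiles()].
#' @param target_cluster Cluster id of interest.
#' @param min_cells Minimum cells in the target cluster (default 10,
#'   compared with >=).
#' @param min_fraction Fraction of the clonotype's cells that must sit in
#'   the target cluster (default 0.60, compared with >).
#' @return Data frame sorted by descending `cells_in_target_cluster` (ties
#'   by CDR3b): `donor_id`, `group`, `cdr3b_aa`, `cells_in_target_cluster`,
#'   `fraction_in_target_cluster`, `total_cells`, `selected`.
#' @export
select_candidates <- function(profiles, target_cluster, min_cells = 10,
                              min_fraction = 0.60) {
  if (nrow(profiles) > 0 && !any(profiles$cluster_id == target_cluster))
    warning(sprintf("target cluster %s absent from all profiles", target_cluster))
  clone_key <- paste(profiles$donor_id, profiles$cdr3b_aa, sep = "\r")
  first <- !duplicated(clone_key)
  out <- data.frame(donor_id = profiles$donor_id[first],
                    group = profiles$group[first],
                    cdr3b_aa = profiles$cdr3b_aa[first],
                    total_cells = profiles$total_cells[first],
                    stringsAsFactors = FALSE)
  in_target <- profiles$cluster_id == target_cluster
  target_n <- stats::setNames(profiles$n_cells[in_target], clone_key[in_target])
  key_out <- paste(out$donor_id, out$cdr3b_aa, sep = "\r")
  out$cells_in_target_cluster <- as.integer(ifelse(is.na(target_n[key_out]), 0L,
                                                   target_n[key_out]))
  out$fraction_in_target_cluster <- out$cells_in_target_cluster / out$total_cells
  out$selected <- out$cells_in_target_cluster >= min_cells &
    out$fraction_in_target_cluster > min_fraction
  out <- out[order(-out$cells_in_target_cluster, out$cdr3b_aa), ]
  rownames(out) <- NULL
  out
}

#' Cohort accounting over a target cluster
#'
#' Per group: number of clonotypes with cells in the target cluster, cell
#' totals there, mean clonotypes per donor (one decimal), percentage of
#' clonotypes expanded ex vivo (>= 2 cells) and percentage of
#' target-cluster cells belonging to expanded clonotypes (one decimal).
#'
#' @param profiles Output of [build_cluster_profiles()].
#' @param target_cluster Cluster id.
#' @return Data frame, one row per group, plus a `pooled` row.
#' @export
cohort_cluster_stats <- function(profiles, target_cluster) {
  p <- profiles[profiles$cluster_id == target_cluster, , drop = FALSE]
  per_group <- function(d, label) {
    data.frame(group = label,
               n_clonotypes = nrow(d),
               n_cells = sum(d$n_cells),
               n_donors = length(unique(d$donor_id)),
               mean_clonotypes_per_donor =
                 round(nrow(d) / max(length(unique(d$donor_id)), 1), 1),
               pct_expanded_clonotypes =
                 round(100 * mean(d$exvivo_expanded), 1),
               pct_cells_from_expanded =
                 round(100 * sum(d$n_cells[d$exvivo_expanded]) /
                         max(sum(d$n_cells), 1), 1),
               stringsAsFactors = FALSE)
  }
  groups <- unique(p$group)
  out <- do.call(rbind, lapply(groups, function(g)
    per_group(p[p$group == g, , drop = FALSE], g)))
  rbind(out, per_group(p, "pooled"))
}

#' VDJ mapping-rate accounting
#'
#' @param rates Data frame with columns `sample_id`, `chain` (TRA/TRB),
#'   `pct_mapped`.
#' @return List with `per_sample` (the input, sorted) and `cohort_mean`
#'   (data frame chain -> unweighted arithmetic mean over samples, two
#'   decimals).
#' @export
vdj_mapping_rates <- function(rates) {
  if (is.null(rates) || nrow(rates) == 0)
    abort_clonoreact("no mapping rates supplied", "clonoreact_validation_error")
  stopifnot(all(c("sample_id", "chain", "pct_mapped") %in% names(rates)))
  means <- tapply(rates$pct_mapped, rates$chain, function(x) round(mean(x), 2))
  list(per_sample = rates[order(rates$chain, rates$sample_id), ],
       cohort_mean = data.frame(chain = names(means),
                                mean_pct_mapped = as.numeric(means),
                                stringsAsFactors = FALSE))
}
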