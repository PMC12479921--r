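# Group-wise expression statistics: cell-level Wilcoxon DE with BH FDR,
# pseudobulk aggregation with per-million normalization, and exact rank
# tests for small-n assay comparisons.

TCR_GENE_PREFIXES <- c("TRAV", "TRAJ", "TRAC", "TRBV", "TRBD", "TRBJ", "TRBC")

#' Remove TCR alpha/beta chain genes
#'
#' Differential expression between clonotype-defined groups is trivially
#' driven by the TCR segment genes themselves; they are removed before
#' testing.
#'
#' @param gene_ids Character vector of gene symbols.
#' @return The ids not matching the TRAV/TRAJ/TRAC/TRBV/TRBD/TRBJ/TRBC
#'   prefixes, in the original order.
#' @export
strip_tcr_genes <- function(gene_ids) {
  drop <- Reduce(`|`, lapply(TCR_GENE_PREFIXES, startsWith, x = gene_ids))
  gene_ids[!drop]
}

#' Library-size normalization with log transform
#'
#' Per cell, counts are scaled to a common library size and
#' log-transformed: value = ln(1 + count * scale / library_size).
#'
#' @param m Gene-by-cell counts matrix (sparse or dense, with dimnames).
#' @param scale Common library size (default 1e4).
#' @return Matrix of the same shape, log-normalized.
#' @export
normalize_cells <- function(m, scale = 1e4) {
  lib <- Matrix::colSums(m)
  zero <- which(lib == 0)
  if (length(zero) > 0)
    abort_clonoreact(sprintf("zero library size for barcode %s",
                             colnames(m)[zero[1]]),
                     "clonoreact_validation_error")
  out <- m %*% Matrix::Diagonal(x = scale / lib)
  out <- log1p(out)
  dimnames(out) <- dimnames(m)
  out
}

# Two-sided rank-sum p for one gene. Exact tie-free enumeration (via the
# Mann-Whitney null distribution) for small groups, else normal
# approximation with tie correction and continuity correction.
rank_sum_p <- function(x, g1_idx, g2_idx, exact_max = 25) {
  vals <- c(x[g1_idx], x[g2_idx])
  n1 <- length(g1_idx); n2 <- length(g2_idx); n <- n1 + n2
  r <- rank(vals)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  nties <- tabulate(match(r, unique(r)))
  has_ties <- any(nties > 1)
  if (n1 <= exact_max && n2 <= exact_max && !has_ties) {
    p <- if (u > n1 * n2 / 2) 2 * stats::pwilcox(u - 1, n1, n2, lower.tail = FALSE)
         else 2 * stats::pwilcox(u, n1, n2)
    return(min(1, p))
  }
  mu <- n1 * n2 / 2
  sigma2 <- (n1 * n2 / 12) * ((n + 1) - sum(nties^3 - nties) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  z <- u - mu
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)
  min(1, 2 * min(stats::pnorm(z), stats::pnorm(z, lower.tail = FALSE)))
}

#' Cell-level Wilcoxon rank-sum differential expression
#'
#' For every gene expressed in at least `min_pct` of cells in one of the
#' two groups: a two-sided Wilcoxon rank-sum p-value on the log-normalized
#' values (exact null distribution when both groups have at most
#' `exact_max` cells and no ties; otherwise normal approximation with tie
#' and continuity correction), an average log2 fold change computed on
#' back-transformed normalized means with pseudocount 1, and
#' Benjamini-Hochberg adjustment over the tested genes. A gene is flagged
#' significant when its |avg_log2fc| exceeds `fc_cutoff` and its adjusted
#' p-value is below `alpha`.
#'
#' @param norm Gene-by-cell matrix from [normalize_cells()] (TCR genes
#'   already stripped).
#' @param labels Group label per cell (exactly two levels).
#' @param group1 Level treated as group 1 (fold changes are group1 over
#'   group2); defaults to the first level.
#' @param fc_cutoff,alpha,min_pct Significance settings (defaults 0.5,
#'   0.05, 0.1).
#' @param exact_max Largest per-group size for the exact null (default 25).
#' @return Data frame, one row per tested gene: `gene`, `avg_log2fc`,
#'   `p_value`, `adj_p_value`, `pct_expr_group1`, `pct_expr_group2`,
#'   `significant_up`, `significant_down`; sorted by `adj_p_value` then
#'   `p_value`.
#' @export
wilcoxon_de <- function(norm, labels, group1 = NULL, fc_cutoff = 0.5,
                        alpha = 0.05, min_pct = 0.1, exact_max = 25) {
  labels <- as.character(labels)
  lev <- unique(labels)
  if (length(lev) != 2)
    abort_clonoreact("exactly two groups required", "clonoreact_validation_error")
  if (is.null(group1)) group1 <- lev[1]
  g1 <- which(labels == group1); g2 <- which(labels != group1)
  if (length(g1) == 0 || length(g2) == 0)
    abort_clonoreact("both groups must be non-empty", "clonoreact_validation_error")
  m <- as.matrix(norm)
  pct1 <- rowMeans(m[, g1, drop = FALSE] > 0)
  pct2 <- rowMeans(m[, g2, drop = FALSE] > 0)
  tested <- which(pmax(pct1, pct2) >= min_pct)
  if (length(tested) == 0) {
    warning("no gene passes the min_pct expression filter")
    return(data.frame(gene = character(), avg_log2fc = numeric(),
                      p_value = numeric(), adj_p_value = numeric(),
                      pct_expr_group1 = numeric(), pct_expr_group2 = numeric(),
                      significant_up = logical(), significant_down = logical()))
  }
  p <- vapply(tested, function(i) rank_sum_p(m[i, ], g1, g2, exact_max),
              numeric(1))
  # fold change on the original (back-transformed) normalized scale
  mean1 <- rowMeans(expm1(m[tested, g1, drop = FALSE]))
  mean2 <- rowMeans(expm1(m[tested, g2, drop = FALSE]))
  lfc <- log2((mean1 + 1) / (mean2 + 1))
  adj <- bh_adjust(p)
  out <- data.frame(gene = rownames(m)[tested], avg_log2fc = lfc,
                    p_value = p, adj_p_value = adj,
                    pct_expr_group1 = pct1[tested], pct_expr_group2 = pct2[tested],
                    significant_up = lfc > fc_cutoff & adj < alpha,
                    significant_down = lfc < -fc_cutoff & adj < alpha,
                    stringsAsFactors = FALSE)
  out <- out[order(out$adj_p_value, out$p_value, out$gene), ]
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate control; output order matches
#' input, values clipped to [0, 1].
#'
#' @param p_values Numeric vector of p-values in [0, 1].
#' @return Adjusted values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (any(!is.finite(p_values) | p_values < 0 | p_values > 1))
    abort_clonoreact("p-values must lie in [0, 1]", "clonoreact_validation_error")
  stats::p.adjust(p_values, method = "BH")
}

#' Pseudobulk aggregation
#'
#' Sums raw counts per (gene, sample): the donor-level counts used for
#' sample-level statistics. Total mass is conserved exactly.
#'
#' @param m Gene-by-cell counts matrix.
#' @param sample_labels Sample (donor) label per cell; no NAs.
#' @return Dense gene-by-sample matrix of summed counts.
#' @export
pseudobulk <- function(m, sample_labels) {
  if (length(sample_labels) != ncol(m))
    abort_clonoreact("one sample label per cell required", "clonoreact_validation_error")
  if (anyNA(sample_labels))
    abort_clonoreact(sprintf("unlabeled cell at column %d",
                             which(is.na(sample_labels))[1]),
                     "clonoreact_validation_error")
  f <- factor(sample_labels)
  design <- Matrix::sparseMatrix(i = seq_along(f), j = as.integer(f), x = 1,
                                 dims = c(length(f), nlevels(f)))
  out <- as.matrix(m %*% design)
  dimnames(out) <- list(rownames(m), levels(f))
  out
}

#' Counts-per-million normalization of a pseudobulk matrix
#'
#' Scales each sample column to a common total of 1e6 (fragments per
#' million), normalizing for differences in fragment counts between
#' samples.
#'
#' @param pb Gene-by-sample pseudobulk matrix.
#' @return Matrix of the same shape; each column sums to 1e6.
#' @export
fpm_normalize <- function(pb) {
  totals <- colSums(pb)
  zero <- which(totals == 0)
  if (length(zero) > 0)
    abort_clonoreact(sprintf("zero total count for sample %s",
                             colnames(pb)[zero[1]]),
                     "clonoreact_validation_error")
  sweep(pb, 2, totals, "/") * 1e6
}

#' Exact paired Wilcoxon signed-rank test
#'
#' Two-sided p-value by full enumeration of the 2^n sign assignments of the
#' absolute differences (average ranks for tied magnitudes; zero
#' differences dropped first). An assignment is at least as extreme as the
#' observed one when its rank sum deviates at least as far from the null
#' mean n(n+1)/4.
#'
#' @param a,b Paired numeric vectors.
#' @param max_n Largest number of nonzero pairs enumerated (default 20).
#' @return Two-sided exact p-value.
#' @export
exact_signed_rank <- function(a, b, max_n = 20) {
  stopifnot(length(a) == length(b))
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    abort_clonoreact("all paired differences are zero: test undefined",
                     "clonoreact_undefined_test_error")
  if (n > max_n)
    abort_clonoreact(sprintf("exact enumeration limited to %d nonzero pairs", max_n),
                     "clonoreact_validation_error")
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  # distribution of the rank sum over all 2^n assignments, on doubled ranks
  # so tie-averaged half-integer ranks stay integral
  r2 <- round(2 * r)
  counts <- c(1, numeric(sum(r2)))
  for (ri in r2) {
    shifted <- c(numeric(ri), counts[seq_len(length(counts) - ri)])
    counts <- counts + shifted
  }
  w_all <- (seq_along(counts) - 1) / 2
  extreme <- abs(w_all - mu) >= abs(w_obs - mu) - 1e-12
  sum(counts[extreme]) / 2^n
}
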