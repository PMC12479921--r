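# Readers and writers for every external format the pipeline touches.
# All downstream modules operate on the checked in-memory types built here.

#' Construct a bulk TCR-beta repertoire sample
#'
#' A `repertoire_sample` holds one sample's clonotype table at one
#' timepoint. Clonotypes are keyed by CDR3-beta amino-acid sequence;
#' frequencies are always recomputed from counts so counts are the single
#' source of truth.
#'
#' @param sample_id,donor_id Sample identifiers.
#' @param timepoint One of `"ex_vivo"`, `"day7"`, `"day14"`.
#' @param clonotypes Data frame with columns `cdr3b_aa`, `count` and
#'   optionally `cdr3b_nt`, `v_call`, `j_call`.
#' @param input_cell_count Optional number of CD8+ T cells used as
#'   sequencing input; required later if a pseudo-frequency must be
#'   assigned to a clonotype undetected ex vivo.
#' @return An object of class `repertoire_sample`: the clonotype data frame
#'   (with recomputed `frequency`), plus metadata attributes and
#'   `total_count`.
#' @export
repertoire_sample <- function(sample_id, donor_id, timepoint, clonotypes,
                              input_cell_count = NULL) {
  timepoint <- match.arg(timepoint, TIMEPOINTS)
  stopifnot(is.data.frame(clonotypes),
            all(c("cdr3b_aa", "count") %in% names(clonotypes)))
  if (anyNA(clonotypes$count) || any(clonotypes$count < 0))
    abort_clonoreact("clonotype counts must be non-negative",
                     "clonoreact_validation_error")
  if (anyDuplicated(clonotypes$cdr3b_aa))
    abort_clonoreact(sprintf("duplicate CDR3b key(s) in sample '%s'", sample_id),
                     "clonoreact_validation_error")
  bad <- !is_valid_cdr3(clonotypes$cdr3b_aa)
  if (any(bad))
    abort_clonoreact(sprintf(
      "CDR3b sequence(s) outside the 20-letter amino-acid alphabet: %s",
      paste(utils::head(clonotypes$cdr3b_aa[bad], 3), collapse = ", ")),
      "clonoreact_validation_error")
  for (col in c("cdr3b_nt", "v_call", "j_call"))
    if (is.null(clonotypes[[col]])) clonotypes[[col]] <- NA_character_
  total <- sum(clonotypes$count)
  clonotypes$frequency <- if (total > 0) clonotypes$count / total else 0
  clonotypes <- clonotypes[order(-clonotypes$count, clonotypes$cdr3b_aa),
                           c("cdr3b_aa", "cdr3b_nt", "v_call", "j_call",
                             "count", "frequency")]
  rownames(clonotypes) <- NULL
  if (!is.null(input_cell_count) && input_cell_count < 1)
    abort_clonoreact("input_cell_count must be a positive integer",
                     "clonoreact_validation_error")
  structure(clonotypes, class = c("repertoire_sample", "data.frame"),
            sample_id = sample_id, donor_id = donor_id,
            timepoint = timepoint, total_count = total,
            input_cell_count = input_cell_count)
}

#' @export
print.repertoire_sample <- function(x, ...) {
  cat(sprintf("<repertoire_sample> %s (donor %s, %s): %d clonotypes, %d reads\n",
              attr(x, "sample_id"), attr(x, "donor_id"), attr(x, "timepoint"),
              nrow(x), attr(x, "total_count")))
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}

AIRR_REQUIRED <- c("sequence_id", "locus", "junction_aa", "v_call", "j_call",
                   "productive", "duplicate_count")

#' Read a bulk repertoire from an AIRR Rearrangement TSV
#'
#' Productive rows of the requested locus are aggregated into clonotypes by
#' CDR3 (junction) amino-acid sequence; nucleotide variants are merged and
#' the V/J calls of the most abundant variant are retained for display.
#' Frequencies are recomputed from the summed `duplicate_count`; any
#' frequency column present in the file is ignored. Extra columns are
#' ignored silently.
#'
#' @param path Path to a tab-separated rearrangement file with columns
#'   `sequence_id`, `locus`, `junction_aa`, `v_call`, `j_call`,
#'   `productive`, `duplicate_count`.
#' @param locus Locus to keep, default `"TRB"`.
#' @param sample_id,donor_id,timepoint,input_cell_count Sample metadata
#'   passed to [repertoire_sample()].
#' @return A [repertoire_sample()].
#' @export
read_airr_repertoire <- function(path, locus = "TRB", sample_id = basename(path),
                                 donor_id = sample_id, timepoint = "ex_vivo",
                                 input_cell_count = NULL) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           check.names = FALSE, comment.char = "#")
  missing_cols <- setdiff(AIRR_REQUIRED, names(tab))
  if (length(missing_cols) > 0)
    abort_clonoreact(sprintf("rearrangement file '%s' lacks required column(s): %s",
                             path, paste(missing_cols, collapse = ", ")),
                     "clonoreact_format_error")
  if (!is.numeric(tab$duplicate_count))
    tab$duplicate_count <- suppressWarnings(as.numeric(tab$duplicate_count))
  neg <- which(is.na(tab$duplicate_count) | tab$duplicate_count < 0)
  if (length(neg) > 0)
    abort_clonoreact(sprintf("invalid duplicate_count at row %d of '%s'",
                             neg[1], path), "clonoreact_validation_error")
  prod <- tab$productive %in% c(TRUE, "TRUE", "True", "true", "T") & tab$locus == locus
  tab <- tab[prod, , drop = FALSE]
  if (nrow(tab) == 0)
    abort_clonoreact(sprintf("no productive %s rearrangements in '%s'", locus, path),
                     "clonoreact_empty_repertoire_error")
  counts <- tapply(tab$duplicate_count, tab$junction_aa, sum)
  # v/j of the most abundant row per clonotype, kept for display only
  ord <- order(tab$junction_aa, -tab$duplicate_count)
  top <- tab[ord, ][!duplicated(tab$junction_aa[ord]), ]
  top <- top[match(names(counts), top$junction_aa), ]
  nt <- if ("junction" %in% names(tab)) top$junction else NA_character_
  clonotypes <- data.frame(cdr3b_aa = names(counts), cdr3b_nt = nt,
                           v_call = top$v_call, j_call = top$j_call,
                           count = as.numeric(counts),
                           stringsAsFactors = FALSE)
  repertoire_sample(sample_id, donor_id, timepoint, clonotypes,
                    input_cell_count)
}

#' Write a repertoire sample as an AIRR Rearrangement TSV
#'
#' One productive row per clonotype; `duplicate_count` carries the clonotype
#' count, so [read_airr_repertoire()] round-trips the table exactly.
#'
#' @param x A [repertoire_sample()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_airr_repertoire <- function(x, path) {
  stopifnot(inherits(x, "repertoire_sample"))
  out <- data.frame(
    sequence_id = sprintf("%s_%06d", attr(x, "sample_id"), seq_len(nrow(x))),
    locus = "TRB",
    junction_aa = x$cdr3b_aa,
    v_call = ifelse(is.na(x$v_call), "TRBV0-0", x$v_call),
    j_call = ifelse(is.na(x$j_call), "TRBJ0-0", x$j_call),
    productive = "TRUE",
    duplicate_count = x$count,
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read 10x-style VDJ contig annotations
#'
#' Summarizes filtered contig annotations per cell barcode: the number of
#' productive TRB and TRA contigs, and the CDR3 amino-acid sequence of the
#' TRB chain when exactly one productive TRB is present (the clonotype key
#' used throughout the pipeline). Chains other than TRA/TRB are ignored
#' with a warning.
#'
#' @param path Comma-separated file with columns `barcode`, `chain`,
#'   `cdr3`, `productive`.
#' @return Data frame with columns `barcode`, `n_productive_trb`,
#'   `n_productive_tra`, `cdr3b_aa` (NA unless exactly one productive TRB).
#' @export
read_contig_annotations <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("barcode", "chain", "cdr3", "productive")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0)
    abort_clonoreact(sprintf("contig file '%s' lacks required column(s): %s",
                             path, paste(missing_cols, collapse = ", ")),
                     "clonoreact_format_error")
  unknown <- !(tab$chain %in% c("TRA", "TRB"))
  if (any(unknown)) {
    warning(sprintf("ignoring %d contig(s) with chain outside {TRA, TRB}",
                    sum(unknown)))
    tab <- tab[!unknown, , drop = FALSE]
  }
  tab$productive <- tab$productive %in% c(TRUE, "TRUE", "True", "true", "T")
  barcodes <- unique(tab$barcode)
  prod <- tab[tab$productive, , drop = FALSE]
  n_trb <- table(factor(prod$barcode[prod$chain == "TRB"], levels = barcodes))
  n_tra <- table(factor(prod$barcode[prod$chain == "TRA"], levels = barcodes))
  trb <- prod[prod$chain == "TRB", , drop = FALSE]
  cdr3b <- vapply(barcodes, function(b) {
    hits <- trb$cdr3[trb$barcode == b]
    if (length(hits) == 1) hits else NA_character_
  }, character(1))
  data.frame(barcode = barcodes,
             n_productive_trb = as.integer(n_trb),
             n_productive_tra = as.integer(n_tra),
             cdr3b_aa = unname(cdr3b),
             stringsAsFactors = FALSE)
}

#' Read a gene-by-cell counts matrix in Matrix Market triplet form
#'
#' Expects a directory holding `matrix.mtx`, `features.tsv` (gene ids) and
#' `barcodes.tsv`, the layout written by droplet-based single-cell
#' pipelines.
#'
#' @param dir Directory path.
#' @return A sparse `dgCMatrix` with gene ids as rownames and barcodes as
#'   colnames.
#' @export
read_counts_mtx <- function(dir) {
  paths <- file.path(dir, c("matrix.mtx", "features.tsv", "barcodes.tsv"))
  for (p in paths)
    if (!file.exists(p))
      abort_clonoreact(sprintf("missing '%s'", p), "clonoreact_format_error")
  m <- tryCatch(Matrix::readMM(paths[1]), error = function(e)
    abort_clonoreact(sprintf("malformed Matrix Market file: %s", conditionMessage(e)),
                     "clonoreact_format_error"))
  genes <- utils::read.delim(paths[2], header = FALSE,
                             stringsAsFactors = FALSE)[[1]]
  cells <- utils::read.delim(paths[3], header = FALSE,
                             stringsAsFactors = FALSE)[[1]]
  if (nrow(m) != length(genes) || ncol(m) != length(cells))
    abort_clonoreact(sprintf(
      "matrix is %d x %d but %d features / %d barcodes listed",
      nrow(m), ncol(m), length(genes), length(cells)),
      "clonoreact_format_error")
  if (anyDuplicated(cells))
    abort_clonoreact("duplicate barcodes in barcodes.tsv",
                     "clonoreact_validation_error")
  if (any(m@x < 0))
    abort_clonoreact("negative entries in counts matrix",
                     "clonoreact_validation_error")
  # symmetric/pattern variants come back as restricted classes; expand to a
  # general sparse matrix so gene/cell dimnames can differ
  m <- methods::as(methods::as(m, "generalMatrix"), "CsparseMatrix")
  dimnames(m) <- list(genes, cells)
  m
}

#' Write a counts matrix in Matrix Market triplet form
#'
#' @param m Sparse or dense gene-by-cell matrix with dimnames.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_counts_mtx <- function(m, dir) {
  stopifnot(!is.null(rownames(m)), !is.null(colnames(m)))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m_sparse <- methods::as(Matrix::Matrix(m, sparse = TRUE), "generalMatrix")
  Matrix::writeMM(m_sparse, file.path(dir, "matrix.mtx"))
  writeLines(rownames(m), file.path(dir, "features.tsv"))
  writeLines(colnames(m), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Read per-cell metadata
#'
#' @param path Tab-separated file with columns `barcode`, `donor_id`,
#'   `group`, `sample_tag`, `cluster_id`, `pct_mito`, `n_genes_detected`.
#' @return Data frame, one row per cell; `cluster_id` may be NA.
#' @export
read_cell_metadata <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  required <- c("barcode", "donor_id", "group", "sample_tag", "cluster_id",
                "pct_mito", "n_genes_detected")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0)
    abort_clonoreact(sprintf("cell metadata '%s' lacks column(s): %s",
                             path, paste(missing_cols, collapse = ", ")),
                     "clonoreact_format_error")
  if (anyDuplicated(tab$barcode))
    abort_clonoreact("duplicate barcodes in cell metadata",
                     "clonoreact_validation_error")
  bad <- !is.na(tab$pct_mito) & (tab$pct_mito < 0 | tab$pct_mito > 100)
  if (any(bad))
    abort_clonoreact(sprintf("pct_mito outside [0,100] for barcode %s",
                             tab$barcode[which(bad)[1]]),
                     "clonoreact_validation_error")
  tab
}

#' Read NFAT-reporter luminescence readouts
#'
#' Groups replicate relative-light-unit (RLU) measurements per TCR and
#' condition. Condition labels are validated against the assay vocabulary:
#' `neurons_stim`, `neurons_unstim`, `neurons_stim_hla_block`, `pbmc`,
#' `transact`, `mock`.
#'
#' @param path Comma-separated file with columns `tcr_id`, `donor_id`,
#'   `group`, `condition`, `replicate`, `rlu`.
#' @return A list of assays, one per TCR, each a list with `tcr_id`,
#'   `donor_id`, `group` and `replicates` (a named list mapping condition
#'   to its numeric RLU vector).
#' @export
read_luminescence <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("tcr_id", "donor_id", "group", "condition", "replicate", "rlu")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0)
    abort_clonoreact(sprintf("luminescence file '%s' lacks column(s): %s",
                             path, paste(missing_cols, collapse = ", ")),
                     "clonoreact_format_error")
  if (nrow(tab) == 0) {
    warning(sprintf("luminescence file '%s' has no data rows", path))
    return(list())
  }
  bad <- !(tab$condition %in% LUM_CONDITIONS)
  if (any(bad))
    abort_clonoreact(sprintf(
      "unknown condition '%s'; allowed: %s", tab$condition[which(bad)[1]],
      paste(LUM_CONDITIONS, collapse = ", ")), "clonoreact_validation_error")
  if (any(!is.finite(tab$rlu) | tab$rlu < 0))
    abort_clonoreact("rlu values must be finite and non-negative",
                     "clonoreact_validation_error")
  lapply(split(tab, tab$tcr_id), function(d) {
    list(tcr_id = d$tcr_id[1], donor_id = d$donor_id[1], group = d$group[1],
         replicates = lapply(split(d$rlu, d$condition), as.numeric))
  })
}

#' Write luminescence readouts
#'
#' Inverse of [read_luminescence()]; one row per replicate.
#'
#' @param assays List of assays as returned by [read_luminescence()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_luminescence <- function(assays, path) {
  rows <- do.call(rbind, lapply(assays, function(a) {
    do.call(rbind, lapply(names(a$replicates), function(cond) {
      data.frame(tcr_id = a$tcr_id, donor_id = a$donor_id, group = a$group,
                 condition = cond,
                 replicate = seq_along(a$replicates[[cond]]),
                 rlu = a$replicates[[cond]], stringsAsFactors = FALSE)
    }))
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
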