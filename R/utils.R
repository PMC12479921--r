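#' @keywords internal
"_PACKAGE"

# Standard amino-acid alphabet used to validate CDR3 sequences.
AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

TIMEPOINTS <- c("ex_vivo", "day7", "day14")
GROUPS <- c("AgD", "Ri_AIE", "HD")
LUM_CONDITIONS <- c("neurons_stim", "neurons_unstim", "neurons_stim_hla_block",
                    "pbmc", "transact", "mock")

abort_clonoreact <- function(msg, class) {
  stop(structure(class = c(class, "clonoreact_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

is_valid_cdr3 <- function(x) {
  nzchar(x) & !is.na(x) &
    vapply(strsplit(x, ""), function(ch) all(ch %in% AA_ALPHABET), logical(1))
}

#' Stable 32-bit seed substream
#'
#' Derives a child seed from a top-level seed and a stream name so that each
#' generator draws from its own reproducible stream and adding a generator
#' does not perturb the others.
#'
#' @param seed Integer top-level seed.
#' @param stream Character stream name.
#' @return An integer seed below 2^31.
#' @keywords internal
substream_seed <- function(seed, stream) {
  # Polynomial rolling hash over the stream name, folded with the seed.
  # Multipliers kept small so every intermediate stays exactly representable
  # as a double (well below 2^53) on any platform.
  h <- 17
  for (code in utf8ToInt(stream)) h <- (h * 131 + code) %% 2147483629
  as.integer((h + as.numeric(seed) * 48271) %% 2147483629)
}

with_substream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(seed, stream))
  expr
}

# Rolling hash of a deparsed object, hex-encoded; used to stamp output
# tables with the configuration they were produced under.
fnv1a_hex <- function(x) {
  h <- 17
  for (code in utf8ToInt(paste(deparse(x), collapse = ";")))
    h <- (h * 131 + code) %% 2147483629
  sprintf("%08x", h)
}

#' Write a pipeline output table
#'
#' Writes a TSV with a header row, preceded by a comment line recording the
#' package version and a hash of the configuration in force, so every output
#' is traceable to the thresholds that produced it.
#'
#' @param x A data frame.
#' @param path Output path.
#' @param config A [clonoreact_config()] list (hashed into the comment line).
#' @param extra_comment Optional additional comment line (no leading "#").
#' @return `path`, invisibly.
#' @export
write_output_tsv <- function(x, path, config = clonoreact_config(),
                             extra_comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  version <- as.character(utils::packageVersion("clonoreact"))
  writeLines(sprintf("# clonoreact %s config=%s", version, fnv1a_hex(config)), con)
  if (!is.null(extra_comment)) writeLines(paste0("# ", extra_comment), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' All tunable thresholds of the pipeline in one object, with the published
#' defaults: expansion fold threshold 9, day-14 reporting floor 0.5%,
#' non-expanded control ceiling 2, cluster-candidate rules (>=10 cells,
#' >60%), single-cell QC cutoffs (single TRB chain, <=10% mitochondrial
#' reads, >=100 genes; genes kept when expressed in >=10 cells), the
#' 5000-RLU reactivity threshold, and the differential-expression cutoffs
#' (|avg log2 fold change| > 0.5, BH-adjusted p < 0.05, min fraction of
#' expressing cells 0.1).
#'
#' @param fold_threshold Expansion fold-change threshold (day 14 vs ex vivo).
#' @param day14_freq_floor Day-14 frequency floor for a reportable expansion.
#' @param control_fold_ceiling Fold ceiling below which a clonotype is a
#'   non-expanded control.
#' @param day7_growth_ratio Day-14/day-7 ratio operationalizing "exponential
#'   increase between day 7 and day 14" for control picking.
#' @param max_pct_mito,min_genes,require_single_trb Cell QC rules.
#' @param min_cells_per_gene Gene filter: minimum expressing cells.
#' @param select_min_cells,select_min_fraction Cluster-candidate rules.
#' @param reactivity_threshold RLU threshold on background-adjusted signals.
#' @param transact_min Minimum adjusted TransAct signal for transfection QC.
#' @param require_hla_block Whether neuron-reactivity requires signal loss
#'   under HLA class I blockade.
#' @param fc_cutoff,alpha,min_pct,norm_scale Differential-expression settings.
#' @return A named list with class `clonoreact_config`.
#' @export
clonoreact_config <- function(fold_threshold = 9,
                              day14_freq_floor = 0.005,
                              control_fold_ceiling = 2,
                              day7_growth_ratio = 2,
                              max_pct_mito = 10,
                              min_genes = 100,
                              require_single_trb = TRUE,
                              min_cells_per_gene = 10,
                              select_min_cells = 10,
                              select_min_fraction = 0.60,
                              reactivity_threshold = 5000,
                              transact_min = 5000,
                              require_hla_block = TRUE,
                              fc_cutoff = 0.5,
                              alpha = 0.05,
                              min_pct = 0.1,
                              norm_scale = 1e4) {
  structure(list(
    fold_threshold = fold_threshold, day14_freq_floor = day14_freq_floor,
    control_fold_ceiling = control_fold_ceiling,
    day7_growth_ratio = day7_growth_ratio,
    max_pct_mito = max_pct_mito, min_genes = min_genes,
    require_single_trb = require_single_trb,
    min_cells_per_gene = min_cells_per_gene,
    select_min_cells = select_min_cells,
    select_min_fraction = select_min_fraction,
    reactivity_threshold = reactivity_threshold, transact_min = transact_min,
    require_hla_block = require_hla_block,
    fc_cutoff = fc_cutoff, alpha = alpha, min_pct = min_pct,
    norm_scale = norm_scale), class = "clonoreact_config")
}
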