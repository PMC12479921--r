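# Repertoire diversity metrics and the coculture expansion caller.

check_frequencies <- function(frequencies, tol = 1e-9) {
  if (length(frequencies) < 1)
    abort_clonoreact("at least one frequency required", "clonoreact_validation_error")
  if (any(!is.finite(frequencies)) || any(frequencies <= 0))
    abort_clonoreact("frequencies must be finite and strictly positive (drop zero clones first)",
                     "clonoreact_domain_error")
  if (abs(sum(frequencies) - 1) > tol)
    abort_clonoreact(sprintf("frequencies sum to %.12f, not 1", sum(frequencies)),
                     "clonoreact_validation_error")
  invisible(frequencies)
}

#' Shannon entropy of a clonotype frequency distribution
#'
#' \eqn{H = -\sum_i F_i \log_2 F_i} over clonotype frequencies \eqn{F_i},
#' in bits. Higher values indicate a more diverse repertoire; a monoclonal
#' repertoire has entropy 0 and a perfectly even repertoire of n clonotypes
#' has entropy \eqn{\log_2 n}.
#'
#' @param frequencies Positive clonotype frequencies summing to 1 (zero
#'   clones must be dropped upstream).
#' @param tol Tolerance on the sum-to-one check.
#' @return Entropy in bits.
#' @export
shannon_entropy <- function(frequencies, tol = 1e-9) {
  check_frequencies(frequencies, tol)
  if (length(frequencies) == 1) return(0)
  -sum(frequencies * log2(frequencies))
}

#' Clonality (1 - Pielou evenness)
#'
#' \eqn{1 - \left(-\sum_i F_i \log_{10} F_i\right) / \log_{10} n} for n
#' clonotypes. 0 for a perfectly even repertoire, approaching 1 as the
#' repertoire becomes monoclonal. Undefined (an error) for n = 1, where the
#' normalizing denominator vanishes.
#'
#' @inheritParams shannon_entropy
#' @return Clonality in [0, 1].
#' @export
clonality <- function(frequencies, tol = 1e-9) {
  check_frequencies(frequencies, tol)
  n <- length(frequencies)
  if (n < 2)
    abort_clonoreact("clonality is undefined for a single clonotype (log10(1) = 0)",
                     "clonoreact_undefined_clonality_error")
  h10 <- -sum(frequencies * log10(frequencies))
  min(max(1 - h10 / log10(n), 0), 1)
}

#' Maximal theoretical (pseudo-)frequency for an undetected clonotype
#'
#' A clonotype detected at day 14 but absent from the ex vivo sample is
#' assigned the highest frequency it could have had while escaping
#' detection: 1 / (number of CD8+ T cells used as sequencing input). With
#' 1e5 input cells this is 1e-5 (0.001%).
#'
#' @param input_cell_count Positive number of input cells.
#' @return The pseudo-frequency.
#' @export
pseudo_frequency <- function(input_cell_count) {
  if (is.null(input_cell_count) || is.na(input_cell_count) || input_cell_count < 1)
    abort_clonoreact(paste("an ex vivo input_cell_count is required to assign a",
                           "pseudo-frequency to clonotypes undetected ex vivo;",
                           "supply it when constructing the ex vivo sample"),
                     "clonoreact_configuration_error")
  1 / input_cell_count
}

#' Fold change of a clonotype frequency across the coculture
#'
#' @param freq_day14 Day-14 frequency.
#' @param freq_exvivo_effective Measured ex vivo frequency, or the
#'   [pseudo_frequency()] when the clonotype was undetected ex vivo. Must
#'   be positive.
#' @return `freq_day14 / freq_exvivo_effective`.
#' @export
fold_change <- function(freq_day14, freq_exvivo_effective) {
  if (any(freq_exvivo_effective <= 0))
    abort_clonoreact("effective ex vivo frequency must be positive; apply pseudo_frequency() first",
                     "clonoreact_domain_error")
  freq_day14 / freq_exvivo_effective
}

#' Assemble a coculture timecourse
#'
#' @param ... `repertoire_sample` objects of one donor at distinct
#'   timepoints (`ex_vivo` required; `day7` optional; `day14` required for
#'   expansion calling).
#' @return A `timecourse_repertoire`: a named list timepoint -> sample.
#' @export
timecourse_repertoire <- function(...) {
  samples <- list(...)
  if (length(samples) == 1 && is.list(samples[[1]]) &&
      !inherits(samples[[1]], "repertoire_sample"))
    samples <- samples[[1]]
  stopifnot(all(vapply(samples, inherits, logical(1), "repertoire_sample")))
  tps <- vapply(samples, attr, character(1), "timepoint")
  if (anyDuplicated(tps))
    abort_clonoreact("duplicate timepoints in timecourse", "clonoreact_validation_error")
  donors <- unique(vapply(samples, attr, character(1), "donor_id"))
  if (length(donors) != 1)
    abort_clonoreact("all samples of a timecourse must share donor_id",
                     "clonoreact_validation_error")
  if (!"ex_vivo" %in% tps)
    abort_clonoreact("an ex_vivo sample is required", "clonoreact_configuration_error")
  structure(stats::setNames(samples, tps), class = "timecourse_repertoire",
            donor_id = donors)
}

#' Call clonotype expansions across a PBMC-neuron coculture timecourse
#'
#' For every clonotype observed at day 14, computes its fold change versus
#' the ex vivo sample, substituting the maximal theoretical
#' [pseudo_frequency()] when the clonotype was undetected ex vivo. A
#' clonotype is `expanded` when the fold change reaches `fold_threshold`;
#' it is additionally `reportable` when its day-14 frequency exceeds
#' `day14_freq_floor` (the >0.5% reporting rule). Clonotypes whose fold
#' change stays below `control_fold_ceiling` are flagged as non-expanded
#' controls; when a day-7 sample is present a control must also lack an
#' exponential day7 -> day14 increase (ratio below `day7_growth_ratio`).
#'
#' @param tc A [timecourse_repertoire()] with ex_vivo and day14 samples.
#' @param fold_threshold Fold-change threshold (default 9, compared with >=).
#' @param day14_freq_floor Day-14 frequency floor for reporting (default 0.005).
#' @param control_fold_ceiling Ceiling below which a clonotype is a
#'   non-expanded control (default 2).
#' @param day7_growth_ratio Day14/day7 ratio above which growth is treated
#'   as exponential (default 2; only used when a day-7 sample exists).
#' @return Data frame of class `expansion_calls`, one row per day-14
#'   clonotype, sorted by descending day-14 frequency (ties broken by
#'   CDR3b), with columns `cdr3b_aa`, `freq_exvivo_effective`,
#'   `pseudo_flag`, `freq_day7`, `freq_day14`, `fold_change`, `expanded`,
#'   `reportable`, `nonexpanded_control`.
#' @export
call_expansions <- function(tc, fold_threshold = 9, day14_freq_floor = 0.005,
                            control_fold_ceiling = 2, day7_growth_ratio = 2) {
  stopifnot(inherits(tc, "timecourse_repertoire"))
  if (is.null(tc$ex_vivo))
    abort_clonoreact("missing ex_vivo sample", "clonoreact_configuration_error")
  if (is.null(tc$day14))
    abort_clonoreact("missing day14 sample", "clonoreact_configuration_error")
  exv <- tc$ex_vivo; d14 <- tc$day14
  if (nrow(d14) == 0) {
    warning("empty day-14 repertoire: no expansion calls")
    return(empty_expansion_calls())
  }
  idx <- match(d14$cdr3b_aa, exv$cdr3b_aa)
  f_ex <- exv$frequency[idx]
  pseudo <- is.na(f_ex)
  if (any(pseudo))
    f_ex[pseudo] <- pseudo_frequency(attr(exv, "input_cell_count"))
  f7 <- if (!is.null(tc$day7)) tc$day7$frequency[match(d14$cdr3b_aa, tc$day7$cdr3b_aa)]
        else rep(NA_real_, nrow(d14))
  fc <- fold_change(d14$frequency, f_ex)
  expanded <- fc >= fold_threshold
  reportable <- expanded & d14$frequency > day14_freq_floor
  control <- fc < control_fold_ceiling
  # a day-7 sample lets us also exclude late exponential risers from controls
  ratio7 <- d14$frequency / f7
  control <- control & (is.na(ratio7) | ratio7 < day7_growth_ratio)
  out <- data.frame(cdr3b_aa = d14$cdr3b_aa,
                    freq_exvivo_effective = f_ex, pseudo_flag = pseudo,
                    freq_day7 = f7, freq_day14 = d14$frequency,
                    fold_change = fc, expanded = expanded,
                    reportable = reportable, nonexpanded_control = control,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$freq_day14, out$cdr3b_aa), ]
  rownames(out) <- NULL
  class(out) <- c("expansion_calls", "data.frame")
  out
}

empty_expansion_calls <- function() {
  structure(data.frame(cdr3b_aa = character(), freq_exvivo_effective = numeric(),
                       pseudo_flag = logical(), freq_day7 = numeric(),
                       freq_day14 = numeric(), fold_change = numeric(),
                       expanded = logical(), reportable = logical(),
                       nonexpanded_control = logical()),
            class = c("expansion_calls", "data.frame"))
}

#' Summary metrics for one repertoire sample
#'
#' @param sample A non-empty [repertoire_sample()].
#' @return One-row data frame: `sample_id`, `n_clonotypes`,
#'   `shannon_entropy_bits`, `clonality` (NA for a single-clonotype
#'   repertoire, where it is undefined), `top_clonotype_freq`.
#' @export
repertoire_summary <- function(sample) {
  stopifnot(inherits(sample, "repertoire_sample"))
  f <- sample$frequency[sample$frequency > 0]
  if (length(f) == 0)
    abort_clonoreact("empty repertoire sample", "clonoreact_validation_error")
  data.frame(sample_id = attr(sample, "sample_id"),
             n_clonotypes = length(f),
             shannon_entropy_bits = shannon_entropy(f),
             clonality = if (length(f) >= 2) clonality(f) else NA_real_,
             top_clonotype_freq = max(f),
             stringsAsFactors = FALSE)
}
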