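# NFAT-reporter reactivity calling.

#' Background-adjust a TCR's luminescence readouts
#'
#' Per condition, the adjusted signal is the replicate mean minus the mean
#' of the TCR's own mock (untransfected-stimulus) wells, floored at zero.
#' The mock condition itself maps to 0.
#'
#' @param assay One assay from [read_luminescence()] (a list with a
#'   `replicates` mapping condition -> RLU vector), or that mapping itself.
#' @return Named numeric vector: condition -> adjusted mean signal.
#' @export
adjust_background <- function(assay) {
  reps <- if (!is.null(assay$replicates)) assay$replicates else assay
  if (is.null(reps$mock))
    abort_clonoreact("mock condition required for background adjustment",
                     "clonoreact_configuration_error")
  bg <- mean(reps$mock)
  adj <- vapply(reps, function(x) max(0, mean(x) - bg), numeric(1))
  adj["mock"] <- 0
  adj
}

#' Transfection quality control via the TransAct positive control
#'
#' @param adjusted Named vector from [adjust_background()].
#' @param transact_min Minimum adjusted TransAct signal (RLU).
#' @return TRUE/FALSE; when no transact condition was run, returns TRUE
#'   with a warning (QC unknown, treated as pass).
#' @export
qc_transfection <- function(adjusted, transact_min = 5000) {
  if (is.na(adjusted["transact"])) {
    warning("no transact condition: transfection QC unknown, treated as pass")
    return(TRUE)
  }
  unname(adjusted["transact"] >= transact_min)
}

#' Call neuron reactivity for one TCR
#'
#' A TCR is neuron-reactive when its background-adjusted signal against
#' stimulated (HLA class I positive) neurons exceeds `threshold` and — when
#' `require_hla_block` — the signal under anti-HLA-ABC blockade falls to or
#' below `threshold`, demonstrating TCR/HLA-mediated activation.
#'
#' @param adjusted Named vector from [adjust_background()]; must include
#'   `neurons_stim`, and `neurons_stim_hla_block` when required.
#' @param threshold Positivity threshold on adjusted signals (default 5000
#'   RLU).
#' @param require_hla_block Demand HLA-dependence for a reactive verdict
#'   (default TRUE); with FALSE, threshold-only positivity is reported.
#' @param tcr_id Identifier carried into the result.
#' @return One-row data frame of class `reactivity_call`: `tcr_id`,
#'   adjusted signals, `neuron_reactive`, `hla_dependent`,
#'   `unstim_above_threshold` (advisory: HLA-independent activation),
#'   `pbmc_positive`/`pbmc_lower_than_neurons` (NA until
#'   [call_pbmc_crossreactivity()]).
#' @export
call_reactivity <- function(adjusted, threshold = 5000,
                            require_hla_block = TRUE, tcr_id = NA_character_) {
  if (is.na(adjusted["neurons_stim"]))
    abort_clonoreact("neurons_stim condition required for a reactivity call",
                     "clonoreact_validation_error")
  if (require_hla_block && is.na(adjusted["neurons_stim_hla_block"]))
    abort_clonoreact("neurons_stim_hla_block condition required (require_hla_block = TRUE)",
                     "clonoreact_validation_error")
  stim <- unname(adjusted["neurons_stim"])
  block <- unname(adjusted["neurons_stim_hla_block"])
  hla_dependent <- !is.na(block) && stim > threshold && block <= threshold
  reactive <- if (require_hla_block) hla_dependent else stim > threshold
  unstim <- unname(adjusted["neurons_unstim"])
  structure(data.frame(
    tcr_id = tcr_id,
    neurons_stim = stim,
    neurons_stim_hla_block = if (is.na(block)) NA_real_ else block,
    neurons_unstim = if (is.na(unstim)) NA_real_ else unstim,
    pbmc = unname(adjusted["pbmc"]),
    transact = unname(adjusted["transact"]),
    neuron_reactive = reactive,
    hla_dependent = isTRUE(hla_dependent),
    unstim_above_threshold = !is.na(unstim) && unstim > threshold,
    pbmc_positive = NA, pbmc_lower_than_neurons = NA,
    stringsAsFactors = FALSE),
    class = c("reactivity_call", "data.frame"))
}

#' PBMC cross-reactivity flags
#'
#' @param call A `reactivity_call` row.
#' @param pbmc_adjusted Adjusted PBMC-condition signal (NA when the
#'   condition was not run, in which case the flags stay NA).
#' @param threshold Positivity threshold (same 5000-RLU default).
#' @return The call with `pbmc_positive` and `pbmc_lower_than_neurons` set.
#' @export
call_pbmc_crossreactivity <- function(call, pbmc_adjusted, threshold = 5000) {
  if (is.na(pbmc_adjusted)) return(call)
  call$pbmc <- pbmc_adjusted
  call$pbmc_positive <- pbmc_adjusted > threshold
  call$pbmc_lower_than_neurons <- call$pbmc_positive &&
    pbmc_adjusted < call$neurons_stim
  call
}

#' Run the full reactivity pipeline over a plate of assays
#'
#' @param assays List from [read_luminescence()].
#' @param threshold,require_hla_block,transact_min See [call_reactivity()]
#'   and [qc_transfection()].
#' @return Data frame, one row per TCR, with `donor_id`, `group`,
#'   `transfection_ok` and all `reactivity_call` columns.
#' @export
call_reactivity_all <- function(assays, threshold = 5000,
                                require_hla_block = TRUE, transact_min = 5000) {
  rows <- lapply(assays, function(a) {
    adj <- adjust_background(a)
    ok <- withCallingHandlers(qc_transfection(adj, transact_min),
                              warning = function(w) invokeRestart("muffleWarning"))
    call <- call_reactivity(adj, threshold, require_hla_block, a$tcr_id)
    call <- call_pbmc_crossreactivity(call, unname(adj["pbmc"]), threshold)
    cbind(data.frame(donor_id = a$donor_id, group = a$group,
                     transfection_ok = ok, stringsAsFactors = FALSE), call)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cohort reactivity summary
#'
#' Fractions are computed over TCRs passing transfection QC; groups with no
#' tested TCR are omitted with a warning.
#'
#' @param calls Data frame from [call_reactivity_all()].
#' @return Data frame per group: `n_tested`, `n_reactive`,
#'   `pct_reactive` (one decimal), `n_pbmc_positive_among_reactive`,
#'   `pct_crossreactive_among_reactive`.
#' @export
summarize_reactivity <- function(calls) {
  calls <- calls[calls$transfection_ok, , drop = FALSE]
  groups <- unique(calls$group)
  rows <- lapply(groups, function(g) {
    d <- calls[calls$group == g, , drop = FALSE]
    if (nrow(d) == 0) {
      warning(sprintf("group %s has no tested TCRs; omitted", g))
      return(NULL)
    }
    reactive <- d[d$neuron_reactive, , drop = FALSE]
    data.frame(group = g, n_tested = nrow(d), n_reactive = nrow(reactive),
               pct_reactive = round(100 * nrow(reactive) / nrow(d), 1),
               n_pbmc_positive_among_reactive = sum(reactive$pbmc_positive %in% TRUE),
               pct_crossreactive_among_reactive = if (nrow(reactive) > 0)
                 round(100 * mean(reactive$pbmc_positive %in% TRUE), 1) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
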