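#!/usr/bin/env Rscript
# Repertoire diversity across the coculture and expansion calling: Shannon
# entropy and 1-Pielou clonality per timepoint, then per-clonotype fold
# changes day 14 vs ex vivo (pseudo-frequency 1/input cells for clonotypes
# undetected ex vivo), expanded at >=9-fold, reportable above 0.5% of the
# day-14 repertoire.

library(clonoreact)

cfg <- clonoreact_config()
fixdir <- file.path("results", "fixtures")
tc <- timecourse_repertoire(
  read_airr_repertoire(file.path(fixdir, "bulk_exvivo.tsv"),
                       sample_id = "exvivo", donor_id = "sim",
                       input_cell_count = 1e5),
  read_airr_repertoire(file.path(fixdir, "bulk_day7.tsv"),
                       sample_id = "day7", donor_id = "sim",
                       timepoint = "day7"),
  read_airr_repertoire(file.path(fixdir, "bulk_day14.tsv"),
                       sample_id = "day14", donor_id = "sim",
                       timepoint = "day14"))

summaries <- do.call(rbind, lapply(tc, repertoire_summary))
print(summaries)
cat(sprintf("clonality day14 / ex vivo: %.2f\n",
            summaries$clonality[summaries$sample_id == "day14"] /
              summaries$clonality[summaries$sample_id == "exvivo"]))

calls <- call_expansions(tc, fold_threshold = cfg$fold_threshold,
                         day14_freq_floor = cfg$day14_freq_floor,
                         control_fold_ceiling = cfg$control_fold_ceiling)
cat(sprintf("%d of %d day-14 clonotypes expanded; %d reportable (>%.1f%% of repertoire)\n",
            sum(calls$expanded), nrow(calls), sum(calls$reportable),
            100 * cfg$day14_freq_floor))
print(head(calls[calls$reportable, ], 10))

write_output_tsv(summaries, "results/repertoire_summaries.tsv", cfg)
write_output_tsv(as.data.frame(calls), "results/expansion_calls.tsv", cfg)
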