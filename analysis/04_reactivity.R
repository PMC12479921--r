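#!/usr/bin/env Rscript
# NFAT-reporter reactivity calling: per-TCR background adjustment against
# its own mock wells, TransAct transfection QC, the 5000-RLU positivity
# threshold with required signal loss under HLA class I blockade, and PBMC
# cross-reactivity flags.

library(clonoreact)

cfg <- clonoreact_config()
assays <- read_luminescence(file.path("results", "fixtures", "luminescence.csv"))
calls <- call_reactivity_all(assays, threshold = cfg$reactivity_threshold,
                             require_hla_block = cfg$require_hla_block,
                             transact_min = cfg$transact_min)
summary <- summarize_reactivity(calls)
cat(sprintf("%d TCRs assayed; %d neuron-reactive\n", nrow(calls),
            sum(calls$neuron_reactive)))
print(summary)

write_output_tsv(calls, "results/reactivity_calls.tsv", cfg)
write_output_tsv(summary, "results/reactivity_summary.tsv", cfg)
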