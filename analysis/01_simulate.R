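#!/usr/bin/env Rscript
# Generate the miniature synthetic study every downstream step consumes:
# a 14-day PBMC-neuron coculture timecourse of bulk TCR-beta repertoires,
# a clonotype-labeled single-cell dataset (3 AgD + 7 Ri-AIE donors, 16
# clusters), a counts matrix with planted fold changes, and an
# NFAT-reporter plate. Planted truth is recorded in the manifest.

library(clonoreact)

fixdir <- file.path("results", "fixtures")
study <- simulate_study(fixdir, seed = 1)

cat("Simulated study written to", fixdir, "\n")
cat(sprintf("  bulk timecourse: %d / %d / %d clonotypes (ex vivo / d7 / d14)\n",
            nrow(study$coculture$timecourse$ex_vivo),
            nrow(study$coculture$timecourse$day7),
            nrow(study$coculture$timecourse$day14)))
cat(sprintf("  planted reactive clones: %d\n",
            length(study$coculture$truth$reactive_clonotypes)))
cat(sprintf("  cells: %d across %d donors; planted cluster-resident clonotypes: %d\n",
            nrow(study$cells$cells),
            length(unique(study$cells$cells$donor_id)),
            length(study$cells$truth$target_cluster_clonotypes)))
cat(sprintf("  counts: %d genes x %d cells, %d genes with planted fold changes\n",
            nrow(study$counts$counts), ncol(study$counts$counts),
            length(study$counts$truth)))
cat(sprintf("  reporter plate: %d TCRs, %d planted reactive\n",
            length(study$luminescence$assays),
            length(study$luminescence$truth$reactive_tcrs)))
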