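#!/usr/bin/env Rscript
# Single-cell QC, clonotype-cluster linkage and candidate selection:
# keep cells with one productive TRB chain, <=10% mitochondrial reads and
# >=100 genes; profile each (donor, CDR3b) clonotype across clusters; and
# select clonotypes with >=10 cells in the target cluster of which >60%
# reside there.

library(clonoreact)

cfg <- clonoreact_config()
fixdir <- file.path("results", "fixtures")
cells <- read_cell_metadata(file.path(fixdir, "cell_metadata.tsv"))

qc <- filter_cells(cells, max_pct_mito = cfg$max_pct_mito,
                   min_genes = cfg$min_genes,
                   require_single_trb = cfg$require_single_trb)
cat(sprintf("QC: kept %d of %d cells (%.1f%%)\n", nrow(qc$kept), nrow(cells),
            100 * nrow(qc$kept) / nrow(cells)))
print(table(qc$removed$reason))

prof <- build_cluster_profiles(qc$kept)
sel <- select_candidates(prof, target_cluster = 1,
                         min_cells = cfg$select_min_cells,
                         min_fraction = cfg$select_min_fraction)
cstats <- cohort_cluster_stats(prof, target_cluster = 1)
cat(sprintf("Cluster 1: %d clonotypes, %d cells; %d candidates selected\n",
            cstats$n_clonotypes[cstats$group == "pooled"],
            cstats$n_cells[cstats$group == "pooled"], sum(sel$selected)))
print(cstats)

write_output_tsv(as.data.frame(table(reason = qc$removed$reason)),
                 "results/qc_removed_reasons.tsv", cfg)
write_output_tsv(prof, "results/cluster_profiles.tsv", cfg)
write_output_tsv(sel, "results/candidate_selection.tsv", cfg)
write_output_tsv(cstats, "results/cohort_cluster_stats.tsv", cfg)
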