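#!/usr/bin/env Rscript
# Group-wise expression statistics: TCR segment genes removed, genes kept
# when expressed in >=10 cells, per-cell log normalization, cell-level
# Wilcoxon rank-sum tests with BH correction (|avg log2FC| > 0.5,
# adjusted p < 0.05), plus donor-level pseudobulk counts scaled to
# fragments per million. Sample-level testing here is rank-based on
# per-million values, not a negative binomial model.

library(clonoreact)

cfg <- clonoreact_config()
counts <- read_counts_mtx(file.path("results", "fixtures", "counts"))
counts <- counts[strip_tcr_genes(rownames(counts)), ]
counts <- filter_genes(counts, min_cells = cfg$min_cells_per_gene)
labels <- ifelse(startsWith(colnames(counts), "AgD"), "AgD", "Ri_AIE")

de <- wilcoxon_de(normalize_cells(counts, scale = cfg$norm_scale), labels,
                  group1 = "Ri_AIE", fc_cutoff = cfg$fc_cutoff,
                  alpha = cfg$alpha, min_pct = cfg$min_pct)
cat(sprintf("tested %d genes: %d up, %d down in Ri_AIE (|log2FC| > %.1f, adj p < %.2f)\n",
            nrow(de), sum(de$significant_up), sum(de$significant_down),
            cfg$fc_cutoff, cfg$alpha))
print(head(de, 10))

# donor-level pseudobulk (cells split into pseudo-donors per group) with
# per-million normalization for dot-plot style summaries
donor <- paste0(labels, "_d", (seq_along(labels) - 1) %% 3 + 1)
pb <- pseudobulk(counts, donor)
fpm <- fpm_normalize(pb)
cat("pseudobulk sample totals:\n")
print(colSums(pb))

write_output_tsv(de, "results/de_results.tsv", cfg,
                 extra_comment = "cell-level Wilcoxon; sample-level NB GLM out of scope")
fpm_df <- data.frame(gene = rownames(fpm), round(fpm, 3), check.names = FALSE)
write_output_tsv(fpm_df, "results/pseudobulk_fpm.tsv", cfg)
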