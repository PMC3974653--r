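#!/usr/bin/env Rscript
# Stage 3 -- cross-species meta-analysis: z-score both expression data
# sets, merge on common gene symbols, drop genes beyond 2-fold between the
# data sets, then correlate each drug's target-gene mean profiles between
# the mouse cell line and the human tumors.

library(pheoscreen)

mouse <- read_table("results/data/expression_mouse.tsv", "expression",
                    species = "mouse")
human <- read_table("results/data/expression_human.tsv", "expression",
                    species = "human")
dmap <- read_table("results/data/drug_target_map.tsv", "drug_target")

qc <- replicate_qc(mouse)
message(sprintf("mouse replicate correlations: %.3f-%.3f",
                min(qc$pearson_r), max(qc$pearson_r)))

merged <- merge_common_genes(zscore_genes(mouse), zscore_genes(human))
message(length(merged$common_genes), " genes in common")
keep <- fold_change_filter(merged, 2)
message(length(keep), " genes below 2-fold between the data sets; ",
        sprintf("overall correlation %.2f",
                overall_gene_correlation(merged, keep)))

corr <- drug_target_correlation(merged, dmap, genes = keep)
message(sprintf("mean per-drug target correlation: %.2f (%d drugs)",
                corr$overall_r, nrow(corr$drugs)))

write_table(corr$drugs, "results/drug_correlations.tsv")
write_table(data.frame(gene = keep), "results/genes_below_2fold.tsv")
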