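#!/usr/bin/env Rscript
# Stage 1 -- simulate every input of the repurposing-screen pipeline with
# known ground truth: a 3,826-compound library on 1536-well plates (8-point
# titrations, 0.5 nM - 46 uM), a paired mouse/human expression data set, a
# 22-drug target map, and a constant-ratio drug-combination assay.

library(pheoscreen)

seed <- 20140403
dir.create("results/data", showWarnings = FALSE, recursive = TRUE)

lib <- gen_screen_library(3826, paper_class_mix(), seed = seed)
message("library: ", nrow(lib), " compounds; planted classes: ",
        paste(names(table(lib$true_class)), table(lib$true_class),
              sep = "=", collapse = ", "))
reads <- gen_plate_reads(lib, noise_sd = 3, seed = seed + 1)
message("plates: ", length(unique(reads$plates$plate_id)),
        " x 1536 wells, columns 1-4 controls")

pair <- gen_expression_pair(1753, rho = 0.86, frac_divergent = 0.18,
                            seed = seed + 2)
dmap <- gen_drug_target_map(22, 2129, 3091, seed = seed + 3)
truth <- combination_truth(dm1 = 5, dm2 = 1000, m1 = 0.603, m2 = 1.145,
                           ratio = 200, ci_true = 0.55, noise_sd = 0.01)
assay <- gen_combination_assay(truth, seed = seed + 4)

write_table(lib, "results/data/library_truth.tsv")
write_table(reads$plates, "results/data/plates.tsv")
write_table(reads$map, "results/data/compound_map.tsv")
write_expression(pair$a, "results/data/expression_mouse.tsv")
write_expression(pair$b, "results/data/expression_human.tsv")
write_table(dmap, "results/data/drug_target_map.tsv")
write_table(assay$single1, "results/data/combo_single_epi.tsv")
write_table(assay$single2, "results/data/combo_single_saha.tsv")
write_table(assay$combo, "results/data/combo_pairs.tsv")
message("inputs written under results/data/")
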