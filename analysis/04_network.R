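#!/usr/bin/env Rscript
# Stage 4 -- drug-target network: build the bipartite drug/target graph,
# score every node by eccentricity centrality (reciprocal of the longest
# shortest path), report the top-20 hubs, and extract the subnetwork
# induced by two example gene sets anchored at hub genes.

library(pheoscreen)

dmap <- read_table("results/data/drug_target_map.tsv", "drug_target")
net <- build_drug_target_network(dmap)
cnt <- network_counts(net)
message("global network: ", cnt$nodes, " nodes and ", cnt$edges, " edges")

scores <- eccentricity_scores(net)
hubs <- top_hubs(scores, 20)
message("top hub: ", hubs$node[1], " (score ", signif(hubs$score[1], 3),
        ", degree ", hubs$degree[1], ")")

# two gene sets built around the top hub genes, standing in for curated
# functional categories
hub_genes <- hubs$node[hubs$kind == "gene"]
gene_pool <- unique(dmap$gene)
sets <- list(set_a = c(hub_genes[seq_len(min(5, length(hub_genes)))],
                       gene_pool[1:20]),
             set_b = gene_pool[21:50])
sub <- extract_geneset_subnetwork(net, sets)
scnt <- network_counts(sub)
message("subnetwork: ", scnt$nodes, " nodes and ", scnt$edges, " edges; ",
        length(attr(sub, "drugs_retained")), " of ",
        length(unique(dmap$drug)), " drugs retained")

write_sif(net, "results/network.sif", "results/node_attributes.tsv", scores)
write_sif(sub, "results/subnetwork.sif")
write_table(hubs, "results/top20_hubs.tsv")
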