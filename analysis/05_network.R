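#!/usr/bin/env Rscript
# Stage 5 — weighted co-occurrence network of the core microbiota.
#
# Soft threshold by the scale-free criterion (R^2 target 0.9, sample-size-
# capped power scan), unsigned adjacency on log relative abundances,
# topological overlap, adaptive tree cut into ecological clusters, module
# eigengenes, kME, and hub taxa (kME > 0.9).

library(coremf)

otu <- read_otu_table("results/data/otu_counts.tsv", kind = "counts")
core_tab <- read.delim("results/core/core_assignment.tsv")
core <- core_tab$otu_id[core_tab$is_core]

net <- build_network(otu, subset = core)

dir.create("results/network", showWarnings = FALSE, recursive = TRUE)
write.table(data.frame(otu_id = names(net$labels), cluster = net$labels),
            "results/network/cluster_labels.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(data.frame(otu_id = rownames(net$kme), net$kme),
            "results/network/kme.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(net$power_report, "results/network/power_report.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
edges <- which(upper.tri(net$adjacency), arr.ind = TRUE)
write.table(data.frame(node1 = rownames(net$adjacency)[edges[, 1]],
                       node2 = rownames(net$adjacency)[edges[, 2]],
                       weight = net$adjacency[edges]),
            "results/network/edges.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
hubs <- data.frame(cluster = rep(names(net$hubs), lengths(net$hubs)),
                   otu_id = unlist(net$hubs), row.names = NULL)
write.table(hubs, "results/network/hub_taxa.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
ca <- data.frame(cluster = rownames(net$cluster_abundance),
                 net$cluster_abundance, check.names = FALSE)
write.table(ca, "results/network/cluster_abundance.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

sizes <- table(net$labels[net$labels > 0])
message(sprintf("soft threshold power %d; %d clusters (sizes %s); %d unassigned",
                net$beta, max(net$labels),
                paste(sizes, collapse = ", "), sum(net$labels == 0)))
message(sprintf("%d hub taxa with kME > 0.9", nrow(hubs)))
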