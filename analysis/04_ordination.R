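#!/usr/bin/env Rscript
# Stage 4 — core-community ordination and ANOSIM.
#
# Bray-Curtis distances on the renormalized core-taxon community, classical
# PCoA, and ANOSIM across zones (global plus all zone pairs; pairwise tests
# on 4+4 samples enumerate all 70 label assignments exactly).

library(coremf)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[1]) else 1L

otu <- read_otu_table("results/data/otu_counts.tsv", kind = "counts")
meta <- read_metadata("results/data/metadata.tsv")
core_tab <- read.delim("results/core/core_assignment.tsv")
core <- core_tab$otu_id[core_tab$is_core]

rel <- to_relative(otu)
sub <- otu_table(sweep(rel$values[core, , drop = FALSE], 2,
                       colSums(rel$values[core, , drop = FALSE]), "/"),
                 kind = "relative")
d <- bray_curtis(sub)
zones <- meta$zone[match(rownames(d), meta$sample_id)]

pc <- pcoa(d)
glob <- anosim(d, zones, n_permutations = 9999, seed = seed)
pairs <- combn(sort(unique(zones)), 2)
pw <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
  sel <- zones %in% pairs[, k]
  a <- anosim(d[sel, sel], zones[sel], seed = seed)
  data.frame(group_a = pairs[1, k], group_b = pairs[2, k],
             R = a$R, p.value = a$p.value, exhaustive = a$exhaustive)
}))

dir.create("results/ordination", showWarnings = FALSE, recursive = TRUE)
coords <- data.frame(sample_id = rownames(pc$coordinates), pc$coordinates)
write.table(coords, "results/ordination/pcoa_coordinates.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(pw, "results/ordination/anosim_pairwise.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

message(sprintf("PCoA1/PCoA2 explain %.2f%% / %.2f%% of core-community variance",
                100 * pc$explained[1], 100 * pc$explained[2]))
message(sprintf("global ANOSIM: R = %.4f, p = %.4f", glob$R, glob$p.value))
for (i in seq_len(nrow(pw)))
  message(sprintf("  %s vs %s: R = %.4f, p = %.4f", pw$group_a[i],
                  pw$group_b[i], pw$R[i], pw$p.value[i]))
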