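#!/usr/bin/env Rscript
# Stage 2 — identify the core microbiota.
#
# Dual criterion: top decile of OTUs by mean relative abundance AND present
# in >= 95% of samples (with 12 samples that means all 12). Reports the core
# count per kingdom, as studies report separate bacterial/fungal core sizes.

library(coremf)

otu <- read_otu_table("results/data/otu_counts.tsv", kind = "counts")
tax <- read_taxonomy("results/data/taxonomy.tsv")

core_tab <- identify_core(otu, top_frac = 0.10, occ_frac = 0.95)
dir.create("results/core", showWarnings = FALSE, recursive = TRUE)
write.table(core_tab, "results/core/core_assignment.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

core <- core_set(core_tab)
kg <- table(tax$kingdom[match(core, tax$otu_id)])
message(sprintf("core microbiota: %d of %d OTUs (%s)",
                length(core), nrow(core_tab),
                paste(names(kg), kg, sep = "=", collapse = ", ")))
message(sprintf("occupancy range among core: %.2f-%.2f; all top-decile by mean abundance",
                min(core_tab$occupancy[core_tab$is_core]),
                max(core_tab$occupancy[core_tab$is_core])))
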