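#!/usr/bin/env Rscript
# Stage 6 — what drives multifunctionality.
#
# (a) Random-forest %IncMSE importance of every taxon for EMF, contrasting
#     core vs non-core taxa (Wilcoxon rank-sum);
# (b) OLS regressions of EMF on each network cluster's abundance;
# (c) copiotroph/oligotroph composition per cluster;
# (d) zone-wise comparisons of cluster abundance.

library(coremf)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[1]) else 1L

otu <- read_otu_table("results/data/otu_counts.tsv", kind = "counts")
tax <- read_taxonomy("results/data/taxonomy.tsv")
meta <- read_metadata("results/data/metadata.tsv")
core_tab <- read.delim("results/core/core_assignment.tsv")
emf_tab <- read.delim("results/emf/emf.tsv")
emf <- setNames(emf_tab$emf, emf_tab$sample_id)
lab_tab <- read.delim("results/network/cluster_labels.tsv")
labels <- setNames(as.integer(lab_tab$cluster), lab_tab$otu_id)
cab <- as.matrix(read.delim("results/network/cluster_abundance.tsv",
                            row.names = 1, check.names = FALSE))

dir.create("results/drivers", showWarnings = FALSE, recursive = TRUE)

X <- t(suppressWarnings(taxon_profiles(otu, transform = "log")))
imp <- rf_importance(X, emf[rownames(X)],
                     is_core = core_tab$is_core[match(colnames(X), core_tab$otu_id)],
                     n_trees = 1000, n_permutations = 0, seed = seed)
write.table(imp, "results/drivers/importance.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
ct <- compare_core_importance(imp)
message(sprintf("core vs non-core %%IncMSE: W = %.0f, p = %.2e (median %.3f vs %.3f)",
                ct$statistic, ct$p.value, ct$median_core, ct$median_other))

reg <- ols_cluster_emf(cab, emf)
write.table(reg, "results/drivers/cluster_emf_regression.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
for (i in seq_len(nrow(reg)))
  message(sprintf("  %s: slope %+.3f, R2 = %.2f, p = %.4f", reg$cluster[i],
                  reg$slope[i], reg$r_squared[i], reg$p.value[i]))

tr <- trophic_ratio(labels, tax)
write.table(tr, "results/drivers/trophic_ratio.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message(paste(sprintf("%s: %.2f%% copiotrophs", tr$cluster, tr$pct_copiotroph),
              collapse = "; "))

zc <- compare_cluster_abundance_by_zone(cab, meta)
zone_rows <- do.call(rbind, lapply(names(zc), function(q) {
  cbind(cluster = q, zc[[q]]$pairwise)
}))
write.table(zone_rows, "results/drivers/cluster_zone_tests.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
sig <- zone_rows[zone_rows$p.value <= 0.05, ]
message(sprintf("%d significant zone contrasts of cluster abundance (p <= 0.05)",
                nrow(sig)))
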