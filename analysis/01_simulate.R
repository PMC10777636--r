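#!/usr/bin/env Rscript
# Stage 1 — generate the synthetic study data.
#
# Emulates the field design: 3 sampling zones (abandoned land AL, root zone
# RZ, transition zone TZ) x 4 replicates, 400 OTUs with 40 planted core taxa
# spread over 5 correlated ecological modules, 10 soil function variables
# driven positively by module 1 and negatively by module 2, 50,000 reads per
# sample. Writes the four input tables plus the planted truth.

library(coremf)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[1]) else 1L

outdir <- "results/data"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

cfg <- synth_config(seed = seed)
d <- synth_community(cfg)

write_otu_table(d$otu, file.path(outdir, "otu_counts.tsv"))
write_taxonomy(d$taxonomy, file.path(outdir, "taxonomy.tsv"))
write_metadata(d$meta, file.path(outdir, "metadata.tsv"))
write_function_table(d$fx, file.path(outdir, "functions.tsv"))
jsonlite::write_json(
  list(seed = seed,
       core_set = d$truth$core_set,
       module_label = as.list(d$truth$module_label),
       driver_sign = d$truth$driver_sign),
  file.path(outdir, "truth.json"), auto_unbox = TRUE, digits = NA)

message(sprintf("simulated %d taxa x %d samples (%d planted core, %d modules) -> %s",
                nrow(d$otu$values), ncol(d$otu$values),
                length(d$truth$core_set), max(d$truth$module_label), outdir))
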