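#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study dataset.
#
# Emulates the field design the pipeline targets: 29 whole-body mosquito
# samples from three villages (VK3/VK5/VK7, 10/10/9), log-normal read depths
# (mean 17,300, SD 13,162 — including samples that will fail the depth
# filter), four village-specific signature OTUs per village at 5-fold
# enrichment among 200 background OTUs, and two "migrant" samples in VK7
# whose expected profiles are dominated by VK3.

suppressPackageStartupMessages(library(microprov))

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 20260922L %% 1000L  # project seed

cfg <- synthetic_config(
  migrant_specs = list(
    list(sample_index = 21L, source_class = "VK3", weight = 0.9),
    list(sample_index = 22L, source_class = "VK3", weight = 0.9)),
  seed = seed)
dat <- generate_dataset(cfg)

write_otu_table(dat$table, file.path(out, "table.tsv"))
write_taxonomy(dat$table$taxonomy, file.path(out, "taxonomy.tsv"))
write_metadata(dat$metadata, file.path(out, "metadata.tsv"))

depths <- sample_depths(dat$table)
message(sprintf("generated %d samples x %d OTUs", n_samples(dat$table),
                n_otus(dat$table)))
message(sprintf("read depths: mean %.0f, SD %.0f, range %d-%d",
                mean(depths), sd(depths), min(depths), max(depths)))
message(sprintf("%d sample(s) below 7500 reads will be filtered next",
                sum(depths < 7500)))
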