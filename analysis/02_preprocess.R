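#!/usr/bin/env Rscript
# Stage 2: depth filtering and rarefaction.
#
# Samples with fewer than 7500 reads are removed (rarefaction curves for
# such libraries have not saturated); the rest are rarefied without
# replacement to the lowest remaining depth so downstream dissimilarities
# and classifiers see equal sampling effort.

suppressPackageStartupMessages(library(microprov))

seed <- 20260922L %% 1000L
tab <- read_otu_table("results/data/table.tsv",
                      taxonomy_path = "results/data/taxonomy.tsv")
md <- read_metadata("results/data/metadata.tsv", tab)

flt <- filter_low_depth(tab, 7500L)
message(sprintf("removed %d of %d samples below 7500 reads: %s",
                length(flt$removed), n_samples(tab),
                paste(flt$removed, collapse = ", ")))
write.table(data.frame(sample_id = flt$removed),
            "results/data/removed_samples.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

floor_depth <- min(sample_depths(flt$table))
rar <- rarefy_table(flt$table, "min", seed = seed)
message(sprintf("rarefied %d samples to %d reads each",
                n_samples(rar), floor_depth))

# rarefaction curve of the shallowest retained sample: has it saturated?
shallow <- names(which.min(sample_depths(flt$table)))
depths <- unique(round(seq(10, floor_depth, length.out = 12)))
curve <- rarefaction_curve(flt$table$counts[shallow, ], depths)
message(sprintf("rarefaction curve for %s: %.1f OTUs at %d reads vs %.1f at %d",
                shallow, curve[length(curve)], max(depths),
                curve[length(curve) - 1], depths[length(depths) - 1]))
write.table(data.frame(depth = depths, expected_otus = curve),
            "results/data/rarefaction_curve.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

write_otu_table(rar, "results/data/table_rarefied.tsv")
write_metadata(md[md$sample_id %in% rownames(rar$counts), ],
               "results/data/metadata_filtered.tsv")
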