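#!/usr/bin/env Rscript
# Stage 6: taxon-focused follow-ups.
#
# Per-village abundance/prevalence of the marker genera (the synthetic
# analogues of Wolbachia, Massilia, Shewanella, Acinetobacter), an
# ordination + PERMANOVA restricted to the Acinetobacter-like OTUs, and a
# screen for genera that are absent everywhere (the analogue of checking
# for human-skin contaminants).

suppressPackageStartupMessages(library(microprov))

seed <- 20260922L %% 1000L
out <- "results/taxa"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

tab <- read_otu_table("results/data/table_rarefied.tsv",
                      taxonomy_path = "results/data/taxonomy.tsv")
md <- read_metadata("results/data/metadata_filtered.tsv", tab)

markers <- list(c("genus", "Wolbachia-like"), c("genus", "Massilia-like"),
                c("genus", "Shewanella-like"),
                c("genus", "Acinetobacter-like"))
rep_out <- taxon_report(tab, md, markers)
write.table(rep_out$per_sample, file.path(out, "marker_per_sample.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(rep_out$by_location, file.path(out, "marker_by_location.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
wb <- rep_out$by_location[rep_out$by_location$taxon == "Wolbachia-like", ]
message("Wolbachia-like abundance by village:")
for (i in seq_len(nrow(wb)))
  message(sprintf("  %s: %.1f-%.1f%% (prevalence %.0f%%)", wb$location[i],
                  100 * wb$min[i], 100 * wb$max[i], 100 * wb$prevalence[i]))

# village structure within the Acinetobacter-like OTUs alone
aci <- subset_by_taxon(tab, "genus", "Acinetobacter-like")
keep <- rowSums(aci$counts) > 0
aci$counts <- aci$counts[keep, , drop = FALSE]
if (n_samples(aci) >= 5 && n_otus(aci) >= 2) {
  d <- distance_matrix(aci)
  grp <- md$location[match(rownames(aci$counts), md$sample_id)]
  pv <- permanova(d, grp, n_perm = 99999L, seed = seed)
  message(sprintf(
    "PERMANOVA on Acinetobacter-like OTUs: F = %.2f, p = %.3g",
    pv$pseudo_F, pv$p))
  jsonlite::write_json(pv, file.path(out, "acinetobacter_permanova.json"),
                       auto_unbox = TRUE, digits = NA)
}

# screen for skin-bacteria genera: expected absent from the synthetic data
skin <- list(c("genus", "Bacillus"), c("genus", "Brevibacterium"),
             c("genus", "Corynebacterium"))
skin_rep <- withCallingHandlers(
  taxon_report(tab, md, skin),
  warning = function(w) { message("note: ", conditionMessage(w))
    invokeRestart("muffleWarning") })
write.table(skin_rep$by_location, file.path(out, "skin_genera.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message("skin-genus screen: max fraction anywhere = ",
        max(skin_rep$by_location$max))
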