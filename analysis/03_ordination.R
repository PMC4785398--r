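#!/usr/bin/env Rscript
# Stage 3: community structure — Horn dissimilarities, clustering, NMDS,
# permutational ANOVA, co-occurrence.
#
# Tests whether microbiota composition separates the villages before any
# supervised modelling: Morisita-Horn dissimilarities, average-linkage
# clustering, 2-D NMDS, and a one-factor PERMANOVA on village labels.

suppressPackageStartupMessages(library(microprov))

seed <- 20260922L %% 1000L
out <- "results/ordination"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

tab <- read_otu_table("results/data/table_rarefied.tsv",
                      taxonomy_path = "results/data/taxonomy.tsv")
md <- read_metadata("results/data/metadata_filtered.tsv", tab)

d <- distance_matrix(tab)
write.table(data.frame(sample_id = rownames(d), d, check.names = FALSE),
            file.path(out, "horn_distances.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

hc <- hierarchical_cluster(d, "average")
ord_ids <- rownames(d)[hc$order]
message("dendrogram leaf order (village prefixes should group): ",
        paste(ord_ids, collapse = " "))

fit <- nmds(d, k = 2, n_starts = 20, seed = seed)
message(sprintf("NMDS stress-1 = %.4f (%s)", fit$stress,
                if (fit$converged) "converged" else "not converged"))
write.table(data.frame(sample_id = rownames(fit$coordinates),
                       fit$coordinates,
                       location = md$location[match(rownames(fit$coordinates),
                                                    md$sample_id)]),
            file.path(out, "nmds_coordinates.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

pv_village <- permanova(d, md$location, n_perm = 99999L, seed = seed)
message(sprintf("PERMANOVA village: pseudo-F = %.2f, p = %.3g",
                pv_village$pseudo_F, pv_village$p))
pv_class <- permanova(d, md$class_label, n_perm = 99999L, seed = seed)
message(sprintf("PERMANOVA sex/diet class: pseudo-F = %.2f, p = %.3g",
                pv_class$pseudo_F, pv_class$p))
jsonlite::write_json(list(village = pv_village, class_label = pv_class),
                     file.path(out, "permanova.json"),
                     auto_unbox = TRUE, digits = NA)

cc <- cooccurrence(tab, level = "genus")
write.table(data.frame(genus = rownames(cc), round(cc, 4),
                       check.names = FALSE),
            file.path(out, "cooccurrence_genus.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf("genus co-occurrence matrix: %d genera", nrow(cc)))
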