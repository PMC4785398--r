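#!/usr/bin/env Rscript
# Stage 4: rdCV random-forest classification of village of capture.
#
# Runs the repeated double cross-validated random forest with inner-loop
# backward OTU elimination and writes the per-observation classification
# probability population, the consensus calls, and the OTU/genus importance
# ranking. 25 repetitions keep this desk-scale; raise n_rep to 200 for a
# full run.

suppressPackageStartupMessages(library(microprov))

seed <- 20260922L %% 1000L
out <- "results/classification"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

tab <- read_otu_table("results/data/table_rarefied.tsv",
                      taxonomy_path = "results/data/taxonomy.tsv")
md <- read_metadata("results/data/metadata_filtered.tsv", tab)
labels <- md$location[match(rownames(tab$counts), md$sample_id)]

cfg <- rdcv_config(n_rep = 25L, forest_size = 64L, seed = seed)
res <- run_rdcv(tab, labels, cfg)
print(res)

write.table(data.frame(sample_id = rownames(res$consensus_prob),
                       true_label = unname(res$labels),
                       consensus_class = unname(res$consensus_class),
                       round(res$consensus_prob, 4), check.names = FALSE),
            file.path(out, "probabilities.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

long <- do.call(rbind, lapply(seq_len(dim(res$prob)[3]), function(r)
  data.frame(sample_id = rep(rownames(res$prob), ncol(res$prob)),
             class = rep(colnames(res$prob), each = nrow(res$prob)),
             repetition = r, p = as.vector(res$prob[, , r]))))
write.table(long, file.path(out, "prob_population.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

mis <- res$labels != res$consensus_class
if (any(mis))
  message("misclassified (candidate migrants): ",
          paste(sprintf("%s (%s -> %s)", names(res$labels)[mis],
                        res$labels[mis], res$consensus_class[mis]),
                collapse = ", "))

imp <- importance_summary(res, tab$taxonomy)
write.table(imp, file.path(out, "importance_genus.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message("top genera by importance rank: ",
        paste(head(imp$genus, 5), collapse = ", "))
message(sprintf("OTUs retained per outer model: median %.0f (range %d-%d)",
                median(res$selected_n_otus), min(res$selected_n_otus),
                max(res$selected_n_otus)))
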