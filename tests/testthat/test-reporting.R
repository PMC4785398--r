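test_that("taxon_report summarizes abundance and prevalence by location", {
  dat <- small_dataset(seed = 61)
  rep_out <- taxon_report(dat$table, dat$metadata,
                          list(c("genus", "Wolbachia-like"),
                               c("genus", "Massilia-like")))
  ps <- rep_out$per_sample
  bl <- rep_out$by_location
  expect_equal(nrow(ps), 2 * 15)
  expect_equal(nrow(bl), 2 * 3)

  # brute-force agreement of the per-location min/max/mean
  wl <- relative_abundance(dat$table, "genus", "Wolbachia-like")
  vk3 <- dat$metadata$sample_id[dat$metadata$location == "VK3"]
  row <- bl[bl$taxon == "Wolbachia-like" & bl$location == "VK3", ]
  expect_equal(row$min, min(wl[vk3]))
  expect_equal(row$max, max(wl[vk3]))
  expect_equal(row$mean, mean(wl[vk3]))
  expect_equal(row$prevalence, mean(wl[vk3] > 0))

  # taxon in every sample of a group -> prevalence 1
  all_there <- taxon_report(dat$table, dat$metadata,
                            list(c("domain", "Bacteria")))$by_location
  expect_equal(all_there$prevalence, rep(1, 3))

  # unknown taxon: zero-filled with a warning, not an error
  expect_warning(
    ghost <- taxon_report(dat$table, dat$metadata,
                          list(c("genus", "Nosuchgenus"))),
    "not found")
  expect_equal(ghost$per_sample$fraction, rep(0, 15))
})

pipeline_config <- function(seed = 5) {
  list(
    seed = seed,
    simulate = list(class_sizes = c(5L, 5L, 5L),
                    n_signature_otus_per_class = 3L,
                    signature_fold_change = 5,
                    n_background_otus = 20L,
                    depth_log_mean = log(1500), depth_log_sd = 0.2),
    preprocess = list(min_reads = 500),
    ordination = list(k = 2, n_starts = 5),
    permanova = list(n_perm = 99),
    classify = list(n_rep = 2, n_outer = 3, n_inner = 3,
                    forest_size = 32),
    permtest = list(n_models = 4, null_n_rep = 1))
}

test_that("run_pipeline emits all report files and is deterministic", {
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  expect_message(run_pipeline(pipeline_config(), out1), "classify")
  suppressMessages(run_pipeline(pipeline_config(), out2))

  expected <- c("table.tsv", "metadata.tsv", "taxonomy.tsv",
                "removed_samples.tsv", "table_rarefied.tsv",
                "distances.tsv", "nmds_coordinates.tsv", "nmds.json",
                "permanova.json", "probabilities.tsv",
                "prob_population.tsv", "misclassified.tsv",
                "importance.tsv", "importance_genus.tsv",
                "h0_counts.tsv", "permtest.json", "manifest.json")
  expect_true(all(file.exists(file.path(out1, expected))))

  # identical config -> byte-identical numeric outputs
  for (f in setdiff(expected, "manifest.json"))
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)),
                     label = f)

  # manifest records md5 of every written file
  man <- jsonlite::read_json(file.path(out1, "manifest.json"))
  expect_equal(unname(unlist(man$files["permtest.json"])),
               unname(tools::md5sum(file.path(out1, "permtest.json"))))
})

test_that("run_pipeline works from a YAML config and on-disk input files", {
  src <- withr::local_tempdir()
  dat <- small_dataset(seed = 9, depth = 1200)
  write_otu_table(dat$table, file.path(src, "table.tsv"))
  write_taxonomy(dat$table$taxonomy, file.path(src, "taxonomy.tsv"))
  write_metadata(dat$metadata, file.path(src, "metadata.tsv"))
  cfg_path <- file.path(src, "config.yaml")
  yaml::write_yaml(list(
    seed = 3,
    input = list(table = file.path(src, "table.tsv"),
                 taxonomy = file.path(src, "taxonomy.tsv"),
                 metadata = file.path(src, "metadata.tsv")),
    permanova = list(n_perm = 99)), cfg_path)
  out <- withr::local_tempdir()
  suppressMessages(run_pipeline(cfg_path, out))
  pv <- jsonlite::read_json(file.path(out, "permanova.json"))
  expect_lt(pv$p, 0.05)  # strong village signal
})

test_that("a failing stage is named and partial outputs are kept", {
  cfg <- pipeline_config()
  cfg$preprocess$min_reads <- 10^9  # removes every sample
  out <- withr::local_tempdir()
  expect_error(suppressMessages(run_pipeline(cfg, out)), "preprocess")
  expect_true(file.exists(file.path(out, "table.tsv")))

  # classification without labels refuses with a precondition error
  src <- withr::local_tempdir()
  dat <- small_dataset(seed = 9, depth = 1200)
  md <- dat$metadata
  md$location <- NA
  write_otu_table(dat$table, file.path(src, "table.tsv"))
  write_metadata(md, file.path(src, "metadata.tsv"))
  cfg2 <- list(seed = 1,
               input = list(table = file.path(src, "table.tsv"),
                            metadata = file.path(src, "metadata.tsv")),
               classify = list(n_rep = 1, n_outer = 3, n_inner = 3,
                               forest_size = 16))
  expect_error(suppressMessages(run_pipeline(cfg2, withr::local_tempdir())),
               "classify")
})
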