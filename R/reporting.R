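#' Per-location abundance report for selected taxa
#'
#' For each requested taxon: the per-sample relative abundance, and per
#' location the min/max/mean fraction and prevalence (fraction of samples
#' with nonzero reads). This is the tabular form behind taxon-focused
#' summaries such as per-village *Wolbachia* abundance ranges or screens
#' for human-skin genera.
#'
#' @param table an [otu_table] with taxonomy.
#' @param metadata metadata data.frame (`sample_id`, `location`, ...).
#' @param taxa list of `c(rank, name)` pairs.
#' @return list with `per_sample` (taxon, rank, sample_id, location,
#'   fraction) and `by_location` (taxon, location, min, max, mean,
#'   prevalence). A taxon absent from the table yields zero rows with a
#'   warning, not an error.
#' @export
taxon_report <- function(table, metadata, taxa) {
  stopifnot(all(metadata$sample_id %in% rownames(table$counts)))
  loc <- setNames(metadata$location, metadata$sample_id)
  per_sample <- list()
  by_loc <- list()
  for (tx in taxa) {
    rank <- tx[[1]]; name <- tx[[2]]
    frac <- relative_abundance(table, rank, name)
    if (all(frac == 0))
      warning("taxon not found in table: ", rank, "=", name, call. = FALSE)
    frac <- frac[metadata$sample_id]
    per_sample[[length(per_sample) + 1L]] <-
      data.frame(taxon = name, rank = rank,
                 sample_id = metadata$sample_id,
                 location = unname(loc[metadata$sample_id]),
                 fraction = unname(frac), stringsAsFactors = FALSE)
    for (l in unique(metadata$location)) {
      f <- frac[metadata$sample_id[metadata$location == l]]
      by_loc[[length(by_loc) + 1L]] <-
        data.frame(taxon = name, rank = rank, location = l,
                   min = min(f), max = max(f), mean = mean(f),
                   prevalence = mean(f > 0), stringsAsFactors = FALSE)
    }
  }
  list(per_sample = do.call(rbind, per_sample),
       by_location = do.call(rbind, by_loc))
}

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full pipeline from a single configuration
#'
#' Executes simulate (or load) -> preprocess -> distances/ordination/
#' permanova -> classify -> permutation test, as configured, writing every
#' numeric output as TSV/JSON plus a run manifest (package version, seeds,
#' config, md5 of every written file) from which the run is reproducible.
#' A stage failure aborts with the failing stage named; outputs of completed
#' stages are retained.
#'
#' @param config a YAML file path or an equivalent nested list. Recognized
#'   blocks: `simulate` (arguments of [synthetic_config()]) or `input`
#'   (`table`, `metadata`, optional `taxonomy` file paths); `preprocess`
#'   (`min_reads`, `rarefy_depth`); `ordination` (`k`, `n_starts`);
#'   `permanova` (`n_perm`); `classify` (arguments of [rdcv_config()]);
#'   `permtest` (`n_models`, `null_n_rep`). Top-level `seed` seeds every
#'   stage lacking its own.
#' @param out_dir output directory (created if missing).
#' @return the output directory path, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_yaml(config)
  stopifnot(is.list(config))
  seed <- if (!is.null(config$seed)) as.integer(config$seed) else 1L
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  log <- function(...) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  # -- data: simulate or load ------------------------------------------------
  if (!is.null(config$simulate)) {
    dat <- stage("simulate", {
      args <- config$simulate
      if (!is.null(args$class_sizes)) args$class_sizes <-
          as.integer(unlist(args$class_sizes))
      if (is.null(args$seed)) args$seed <- seed
      generate_dataset(do.call(synthetic_config, args))
    })
    table <- dat$table
    metadata <- dat$metadata
    log("simulate: %d samples x %d OTUs", n_samples(table), n_otus(table))
  } else if (!is.null(config$input)) {
    table <- stage("load", read_otu_table(
      config$input$table, taxonomy_path = config$input$taxonomy))
    metadata <- stage("load", read_metadata(config$input$metadata, table))
  } else stop("config needs a 'simulate' or 'input' block")
  written <- c(written,
               write_otu_table(table, file.path(out_dir, "table.tsv")),
               write_metadata(metadata, file.path(out_dir, "metadata.tsv")))
  if (!is.null(table$taxonomy))
    written <- c(written, write_taxonomy(
      table$taxonomy, file.path(out_dir, "taxonomy.tsv")))

  # -- preprocess ------------------------------------------------------------
  pp <- config$preprocess
  if (!is.null(pp)) {
    min_reads <- if (!is.null(pp$min_reads)) pp$min_reads else 7500L
    flt <- stage("preprocess", filter_low_depth(table, min_reads))
    log("preprocess: removed %d sample(s) below %d reads",
        length(flt$removed), min_reads)
    written <- c(written, .write_tsv(
      data.frame(sample_id = flt$removed),
      file.path(out_dir, "removed_samples.tsv")))
    depth <- if (!is.null(pp$rarefy_depth)) pp$rarefy_depth else "min"
    table <- stage("preprocess",
                   rarefy_table(flt$table, depth = depth, seed = seed))
    metadata <- metadata[metadata$sample_id %in% rownames(table$counts), ]
    written <- c(written, write_otu_table(
      table, file.path(out_dir, "table_rarefied.tsv")))
  }

  # -- distances / ordination / permanova ------------------------------------
  d <- NULL
  if (!is.null(config$ordination) || !is.null(config$permanova)) {
    d <- stage("distances", distance_matrix(table))
    written <- c(written, .write_tsv(
      data.frame(sample_id = rownames(d), d, check.names = FALSE),
      file.path(out_dir, "distances.tsv")))
  }
  if (!is.null(config$ordination)) {
    oc <- config$ordination
    ord <- stage("ordinate", nmds(
      d, k = if (!is.null(oc$k)) oc$k else 2L,
      n_starts = if (!is.null(oc$n_starts)) oc$n_starts else 20L,
      seed = seed))
    log("ordinate: stress-1 = %.4f", ord$stress)
    written <- c(written, .write_tsv(
      data.frame(sample_id = rownames(ord$coordinates), ord$coordinates,
                 check.names = FALSE),
      file.path(out_dir, "nmds_coordinates.tsv")))
    write_json(list(stress = ord$stress, converged = ord$converged,
                    n_starts = ord$n_starts_used, seed = ord$seed),
               file.path(out_dir, "nmds.json"), auto_unbox = TRUE)
    written <- c(written, file.path(out_dir, "nmds.json"))
  }
  if (!is.null(config$permanova)) {
    pv <- stage("permanova", permanova(
      d, metadata$location,
      n_perm = if (!is.null(config$permanova$n_perm))
        config$permanova$n_perm else 9999L,
      seed = seed))
    log("permanova: F = %.2f, p = %.4g", pv$pseudo_F, pv$p)
    write_json(pv, file.path(out_dir, "permanova.json"), auto_unbox = TRUE,
               digits = NA)
    written <- c(written, file.path(out_dir, "permanova.json"))
  }

  # -- classify --------------------------------------------------------------
  rdcv_res <- NULL
  rc <- NULL
  if (!is.null(config$classify)) {
    if (is.null(metadata$location) || anyNA(metadata$location))
      stop("stage 'classify' failed: sample labels (location) missing",
           call. = FALSE)
    args <- config$classify
    if (is.null(args$seed)) args$seed <- seed
    rc <- do.call(rdcv_config, args)
    rdcv_res <- stage("classify", run_rdcv(
      table, metadata$location[match(rownames(table$counts),
                                     metadata$sample_id)], rc))
    log("classify: %d/%d misclassified", rdcv_res$n_misclassified,
        n_samples(table))
    written <- c(written, .write_tsv(
      data.frame(sample_id = rownames(rdcv_res$consensus_prob),
                 true_label = unname(rdcv_res$labels),
                 consensus_class = unname(rdcv_res$consensus_class),
                 rdcv_res$consensus_prob, check.names = FALSE),
      file.path(out_dir, "probabilities.tsv")))
    pp_long <- do.call(rbind, lapply(seq_len(dim(rdcv_res$prob)[3]),
      function(r) data.frame(
        sample_id = rep(rownames(rdcv_res$prob), ncol(rdcv_res$prob)),
        class = rep(colnames(rdcv_res$prob), each = nrow(rdcv_res$prob)),
        repetition = r, p = as.vector(rdcv_res$prob[, , r]))))
    written <- c(written, .write_tsv(
      pp_long, file.path(out_dir, "prob_population.tsv")))
    mis <- rdcv_res$labels != rdcv_res$consensus_class
    written <- c(written, .write_tsv(
      data.frame(sample_id = names(rdcv_res$labels)[mis],
                 true_label = unname(rdcv_res$labels[mis]),
                 consensus_class = unname(rdcv_res$consensus_class[mis])),
      file.path(out_dir, "misclassified.tsv")))
    imp <- data.frame(otu_id = names(rdcv_res$importance_rank),
                      avg_rank = unname(rdcv_res$importance_rank))
    imp <- imp[order(imp$avg_rank), ]
    written <- c(written, .write_tsv(
      imp, file.path(out_dir, "importance.tsv")))
    if (!is.null(table$taxonomy))
      written <- c(written, .write_tsv(
        importance_summary(rdcv_res, table$taxonomy),
        file.path(out_dir, "importance_genus.tsv")))
  }

  # -- permutation test ------------------------------------------------------
  if (!is.null(config$permtest)) {
    if (is.null(rdcv_res))
      stop("stage 'permtest' failed: requires the classify stage",
           call. = FALSE)
    pt_cfg <- config$permtest
    h0 <- stage("permtest", build_h0(
      table, rdcv_res$labels, rc,
      n_models = if (!is.null(pt_cfg$n_models)) pt_cfg$n_models else 400L,
      null_n_rep = if (!is.null(pt_cfg$null_n_rep))
        pt_cfg$null_n_rep else 1L,
      seed = seed))
    p <- h0_pvalue(rdcv_res$n_misclassified, h0)
    log("permtest: H0 mean %.2f (predicted %.2f), p = %.3g", h0$mean,
        predicted_h0_mean(as.vector(table(rdcv_res$labels))), p)
    written <- c(written, .write_tsv(
      data.frame(model = seq_along(h0$counts),
                 misclassifications = h0$counts),
      file.path(out_dir, "h0_counts.tsv")))
    write_json(list(mean = h0$mean, sd = h0$sd,
                    predicted_mean = predicted_h0_mean(
                      as.vector(table(rdcv_res$labels))),
                    df = h0$df, n_models = h0$n_models,
                    skewness = h0$skewness,
                    excess_kurtosis = h0$excess_kurtosis,
                    p_value = p),
               file.path(out_dir, "permtest.json"), auto_unbox = TRUE,
               digits = NA)
    written <- c(written, file.path(out_dir, "permtest.json"))
  }

  # -- manifest --------------------------------------------------------------
  manifest <- list(
    package = "microprov",
    version = as.character(utils::packageVersion("microprov")),
    r_version = R.version.string,
    seed = seed,
    config = config,
    files = as.list(setNames(unname(md5sum(written)), basename(written))))
  write_json(manifest, file.path(out_dir, "manifest.json"),
             auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
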