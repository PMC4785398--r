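#' Permuted-label null-calibration study
#'
#' Generates one synthetic village-structured OTU table, rarefies it to its
#' minimum sample depth, and builds a permuted-label H0 misclassification
#' population with [build_h0()]. A well-behaved (non-overfitting) rdCV
#' procedure yields a null mean at [predicted_h0_mean()] of the class sizes
#' — for the default 10/10/9 design, 19.31 misclassifications of 29.
#'
#' The default problem size is deliberately modest: the null mean depends
#' only on the class sizes, not on the OTU-table width or forest size, so
#' the null substrate uses 52 OTUs (12 signature + 40 background) and
#' 32-tree forests with a single repetition per null model.
#'
#' @param n_models number of permuted-label models.
#' @param class_sizes samples per village.
#' @param n_background_otus background OTUs in the null substrate.
#' @param forest_size trees per null forest.
#' @param seed master seed for generation, rarefaction and null models.
#' @return an `h0_population` (see [build_h0()]).
#' @export
h0_calibration_study <- function(n_models = 200L,
                                 class_sizes = c(10L, 10L, 9L),
                                 n_background_otus = 40L,
                                 forest_size = 32L, seed = 1L) {
  dat <- generate_dataset(synthetic_config(
    class_sizes = class_sizes, n_background_otus = n_background_otus,
    seed = seed))
  tab <- rarefy_table(dat$table, "min", seed = seed)
  cfg <- rdcv_config(forest_size = forest_size, seed = seed)
  build_h0(tab, dat$metadata$location, cfg, n_models = n_models,
           null_n_rep = 1L, seed = seed)
}

#' Classification power study on signature-structured tables
#'
#' Repeatedly generates synthetic OTU tables under the default study
#' conditions (29 samples in villages of 10/10/9, four signature OTUs per
#' village at five-fold enrichment, 200 background OTUs, realistic
#' log-normal depth variation), rarefies each to its minimum sample depth,
#' runs the full rdCV classifier and records the consensus accuracy — the
#' fraction of samples whose repetition-mean class probability assigns the
#' true village.
#'
#' @param n_datasets number of independent synthetic datasets.
#' @param n_rep rdCV repetitions per dataset.
#' @param forest_size trees per forest.
#' @param seed master seed; dataset `i` uses `seed + i`.
#' @param config_args extra arguments passed to [synthetic_config()].
#' @return numeric vector of per-dataset consensus accuracies in `[0, 1]`.
#' @export
classification_power_study <- function(n_datasets = 10L, n_rep = 25L,
                                       forest_size = 50L, seed = 1L,
                                       config_args = list()) {
  vapply(seq_len(n_datasets), function(i) {
    args <- modifyList(list(seed = seed + i), config_args)
    dat <- generate_dataset(do.call(synthetic_config, args))
    tab <- rarefy_table(dat$table, "min", seed = seed + i)
    res <- run_rdcv(tab, dat$metadata$location,
                    rdcv_config(n_rep = n_rep, forest_size = forest_size,
                                seed = seed + i))
    1 - res$n_misclassified / n_samples(tab)
  }, numeric(1))
}
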