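#' Log-normal parameters from natural-scale moments
#'
#' Method-of-moments fit: returns the `meanlog`/`sdlog` of the log-normal
#' distribution with the given natural-scale mean and standard deviation.
#' Used to parameterize per-sample sequencing depth from the depth mean and
#' SD observed in whole-body mosquito 16S data (mean 17,300, SD 13,161.83
#' reads per mosquito), so that the simulated depth spread includes samples
#' below typical filtering thresholds.
#'
#' @param mean,sd natural-scale mean and standard deviation (both > 0).
#' @return list with `meanlog` and `sdlog`.
#' @export
lnorm_from_moments <- function(mean, sd) {
  stopifnot(mean > 0, sd > 0)
  s2 <- log(1 + (sd / mean)^2)
  list(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

#' Configuration for the synthetic OTU-table generator
#'
#' Defaults emulate the study design the pipeline is meant for: 29 mosquito
#' samples from three villages (10/10/9), four location-specific signature
#' OTUs per village at five-fold relative-abundance enrichment, 200
#' background OTUs with log-normally spread baseline abundances (a long tail
#' of rare OTUs plus a few dominant ones), and log-normal per-sample read
#' depths matching a mean of 17,300 and SD of 13,161.83 reads.
#'
#' @param class_sizes integer vector, samples per location; at least one
#'   sample per location.
#' @param n_signature_otus_per_class number of signature OTUs injected per
#'   location.
#' @param signature_fold_change ratio (>= 1) of a signature OTU's expected
#'   relative abundance in its home location versus elsewhere; 1 means no
#'   location signal at all.
#' @param n_background_otus number of background OTUs shared by all
#'   locations.
#' @param background_log_abundance_sd log-scale SD of baseline OTU mean
#'   abundances (log-normal); larger values give a longer rare-OTU tail.
#' @param depth_mean,depth_sd natural-scale mean/SD of per-sample read
#'   depth; converted by [lnorm_from_moments()]. Ignored if
#'   `depth_log_mean`/`depth_log_sd` are supplied directly.
#' @param depth_log_mean,depth_log_sd optional explicit log-normal depth
#'   parameters.
#' @param migrant_specs list of `list(sample_index, source_class, weight)`
#'   entries: the given sample draws its counts from the convex combination
#'   `weight * source-location profile + (1 - weight) * home profile`,
#'   emulating an individual that recently flew in from another village.
#'   `source_class` is a location index or name.
#' @param overdispersion non-negative; 0 (default) draws counts multinomially
#'   given depth, > 0 adds Dirichlet noise with concentration
#'   `profile / overdispersion` (smaller totals = more sample-to-sample
#'   variability than multinomial).
#' @param seed integer seed; generation is fully deterministic given the
#'   config.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(class_sizes = c(10L, 10L, 9L),
                             n_signature_otus_per_class = 4L,
                             signature_fold_change = 5,
                             n_background_otus = 200L,
                             background_log_abundance_sd = 1.5,
                             depth_mean = 17300,
                             depth_sd = 13161.83,
                             depth_log_mean = NULL,
                             depth_log_sd = NULL,
                             migrant_specs = list(),
                             overdispersion = 0,
                             seed = 1L) {
  if (length(class_sizes) < 1 || any(class_sizes < 1) ||
      any(class_sizes != round(class_sizes)))
    stop("class_sizes must be positive integers (empty class not allowed)")
  if (signature_fold_change < 1)
    stop("signature_fold_change must be >= 1")
  if (n_signature_otus_per_class < 0)
    stop("n_signature_otus_per_class must be non-negative")
  if (n_background_otus < 1) stop("n_background_otus must be positive")
  if (background_log_abundance_sd <= 0)
    stop("background_log_abundance_sd must be > 0")
  if (overdispersion < 0) stop("overdispersion must be >= 0")
  if (is.null(depth_log_mean) || is.null(depth_log_sd)) {
    lm <- lnorm_from_moments(depth_mean, depth_sd)
    depth_log_mean <- lm$meanlog
    depth_log_sd <- lm$sdlog
  }
  n <- sum(class_sizes)
  for (ms in migrant_specs) {
    stopifnot(is.list(ms), all(c("sample_index", "source_class", "weight")
                               %in% names(ms)))
    if (ms$sample_index < 1 || ms$sample_index > n)
      stop("migrant sample_index out of range: ", ms$sample_index)
    if (ms$weight < 0 || ms$weight > 1)
      stop("migrant weight must be in [0, 1]")
  }
  structure(list(class_sizes = as.integer(class_sizes),
                 n_signature_otus_per_class =
                   as.integer(n_signature_otus_per_class),
                 signature_fold_change = signature_fold_change,
                 n_background_otus = as.integer(n_background_otus),
                 background_log_abundance_sd = background_log_abundance_sd,
                 depth_log_mean = depth_log_mean,
                 depth_log_sd = depth_log_sd,
                 migrant_specs = migrant_specs,
                 overdispersion = overdispersion,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# Marker genera for signature OTUs, one lineage each; named after the taxa
# that discriminate villages in wild An. gambiae microbiota.
.marker_lineages <- c(
  "Massilia-like" =
    "Bacteria;Proteobacteria;Betaproteobacteria;Burkholderiales;Oxalobacteraceae;Massilia-like",
  "Wolbachia-like" =
    "Bacteria;Proteobacteria;Alphaproteobacteria;Rickettsiales;Anaplasmataceae;Wolbachia-like",
  "Shewanella-like" =
    "Bacteria;Proteobacteria;Gammaproteobacteria;Alteromonadales;Shewanellaceae;Shewanella-like",
  "Acinetobacter-like" =
    "Bacteria;Proteobacteria;Gammaproteobacteria;Pseudomonadales;Moraxellaceae;Acinetobacter-like")

.location_names <- function(k) {
  if (k <= 3) c("VK3", "VK5", "VK7")[seq_len(k)] else paste0("L", seq_len(k))
}

#' Mix a migrant's expected community profile
#'
#' Expected-profile convex combination `weight * source + (1 - weight) *
#' home`: a recently arrived individual carries mostly its source-location
#' flora. Migrants are defined at the expected-profile level (not by
#' resampling reads), matching the interpretation of mixed exposure
#' histories.
#'
#' @param home_profile,source_profile non-negative vectors summing to 1.
#' @param weight mixing weight in `[0, 1]` toward the source profile.
#' @return probability vector summing to 1.
#' @export
generate_migrant_profile <- function(home_profile, source_profile, weight) {
  if (weight < 0 || weight > 1) stop("weight must be in [0, 1]")
  if (length(home_profile) != length(source_profile))
    stop("profiles must have equal length")
  if (any(home_profile < 0) || any(source_profile < 0))
    stop("profiles must be non-negative")
  if (abs(sum(home_profile) - 1) > 1e-6 ||
      abs(sum(source_profile) - 1) > 1e-6)
    stop("profiles must sum to 1")
  weight * source_profile + (1 - weight) * home_profile
}

#' Generate a synthetic OTU table with village structure
#'
#' Draws a dataset with the statistical structure the downstream analyses
#' assume: each location has an expected relative-abundance profile equal to
#' a shared log-normal background in which that location's signature OTUs
#' are enriched `signature_fold_change`-fold; per-sample read depths are
#' log-normal; counts are multinomial given depth (optionally
#' Dirichlet-overdispersed); migrant samples draw from a mixed profile.
#' Signature OTUs are annotated to marker genera (Massilia-like,
#' Wolbachia-like, Shewanella-like, Acinetobacter-like, cycled), background
#' OTUs to generic lineages.
#'
#' @param config a [synthetic_config()].
#' @return list with `table` (an [otu_table] with taxonomy), `metadata`
#'   (data.frame: sample_id, location, class_label, pooled) and `profiles`
#'   (locations x OTUs expected relative-abundance matrix).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  k <- length(config$class_sizes)
  locs <- .location_names(k)
  n <- sum(config$class_sizes)
  ns <- config$n_signature_otus_per_class
  p <- config$n_background_otus + k * ns

  sig_ids <- if (ns > 0)
    sprintf("OTU_sig_%s_%d", rep(locs, each = ns), rep(seq_len(ns), k))
  else character(0)
  bg_ids <- sprintf("OTU_bg_%03d", seq_len(config$n_background_otus))
  otu_ids <- c(sig_ids, bg_ids)

  marker <- names(.marker_lineages)
  sig_tax <- if (ns > 0)
    setNames(.marker_lineages[marker[(seq_len(ns) - 1) %% 4 + 1]][
      rep(seq_len(ns), k)], sig_ids)
  else character(0)
  bg_tax <- setNames(
    sprintf("Bacteria;Phylum_%d;Class_%d;Order_%d;Family_%d;Genus_bg_%03d",
            (seq_along(bg_ids) - 1) %% 8 + 1, (seq_along(bg_ids) - 1) %% 8 + 1,
            (seq_along(bg_ids) - 1) %% 16 + 1, (seq_along(bg_ids) - 1) %% 16 + 1,
            seq_along(bg_ids)),
    bg_ids)
  taxonomy <- c(sig_tax, bg_tax)

  # Baseline expected abundances, shared across locations.
  base <- rlnorm(p, meanlog = 0, sdlog = config$background_log_abundance_sd)
  names(base) <- otu_ids
  profiles <- matrix(rep(base, each = k), nrow = k, dimnames =
                       list(locs, otu_ids))
  if (ns > 0) {
    for (ci in seq_len(k)) {
      own <- sprintf("OTU_sig_%s_%d", locs[ci], seq_len(ns))
      profiles[ci, own] <- profiles[ci, own] * config$signature_fold_change
    }
  }
  profiles <- profiles / rowSums(profiles)

  class_of <- rep(seq_len(k), config$class_sizes)
  sample_ids <- unlist(lapply(seq_len(k), function(ci)
    sprintf("%s_%02d", locs[ci], seq_len(config$class_sizes[ci]))))

  depths <- pmax(1, round(rlnorm(n, config$depth_log_mean,
                                 config$depth_log_sd)))

  expected <- profiles[class_of, , drop = FALSE]
  for (ms in config$migrant_specs) {
    src <- ms$source_class
    if (is.character(src)) src <- match(src, locs)
    if (is.na(src) || src < 1 || src > k)
      stop("unknown migrant source_class")
    i <- ms$sample_index
    expected[i, ] <- generate_migrant_profile(expected[i, ],
                                              profiles[src, ], ms$weight)
  }

  counts <- matrix(0L, n, p, dimnames = list(sample_ids, otu_ids))
  for (i in seq_len(n)) {
    prob <- expected[i, ]
    if (config$overdispersion > 0) {
      g <- rgamma(p, shape = prob / config$overdispersion)
      if (sum(g) == 0) g <- prob
      prob <- g / sum(g)
    }
    counts[i, ] <- as.integer(rmultinom(1, depths[i], prob))
  }

  class_label <- unlist(lapply(config$class_sizes, function(m)
    rep(c("FNBF", "FBF", "M"), length.out = m)))
  metadata <- data.frame(sample_id = sample_ids,
                         location = locs[class_of],
                         class_label = class_label,
                         pooled = class_label == "M",
                         stringsAsFactors = FALSE)

  list(table = otu_table(counts, taxonomy = taxonomy),
       metadata = metadata,
       profiles = profiles)
}
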