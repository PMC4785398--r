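#' Remove low-depth samples
#'
#' Drops every sample with fewer than `min_reads` total reads; a sample with
#' exactly `min_reads` reads is retained. The default threshold of 7500
#' reads reflects typical rarefaction-curve saturation for whole-body
#' mosquito 16S libraries.
#'
#' @param table an [otu_table].
#' @param min_reads positive integer depth threshold.
#' @return list with `table` (retained samples, original order) and
#'   `removed` (ids of dropped samples, sorted by depth ascending).
#' @export
filter_low_depth <- function(table, min_reads = 7500L) {
  stopifnot(min_reads > 0)
  depths <- sample_depths(table)
  drop <- depths < min_reads
  removed <- names(sort(depths[drop]))
  list(table = otu_table(table$counts[!drop, , drop = FALSE],
                         taxonomy = table$taxonomy),
       removed = removed)
}

#' Rarefy an OTU table to a common depth
#'
#' Subsamples each sample's reads without replacement (multivariate
#' hypergeometric) so every row sums to exactly `depth`; removes
#' depth artifacts before dissimilarity and classification analyses.
#'
#' @param table an [otu_table].
#' @param depth target depth, or `"min"` for the lowest sample depth.
#' @param seed integer seed; the subsample is deterministic given the seed.
#' @return an [otu_table] with equal row sums.
#' @export
rarefy_table <- function(table, depth = "min", seed = 1L) {
  depths <- sample_depths(table)
  if (identical(depth, "min")) depth <- min(depths)
  depth <- as.integer(depth)
  if (depth < 1) stop("depth must be positive")
  if (any(depths < depth))
    stop("depth ", depth, " exceeds total reads of sample(s): ",
         paste(names(depths)[depths < depth], collapse = ", "))
  set.seed(seed)
  # rrarefy heuristically warns when counts look unusually large; harmless here
  out <- suppressWarnings(rrarefy(table$counts, sample = depth))
  storage.mode(out) <- "integer"
  otu_table(out, taxonomy = table$taxonomy)
}

#' Rarefaction curve: expected OTU richness at reduced depth
#'
#' For one sample's count vector, the expected number of OTUs observed in a
#' without-replacement subsample of `d` reads is
#' `E[S(d)] = sum_i (1 - choose(N - N_i, d) / choose(N, d))`, the
#' hypergeometric expectation, evaluated in log space. `mode = "montecarlo"`
#' estimates the same quantity by averaging observed richness over `reps`
#' random subsamples.
#'
#' @param sample_counts non-negative integer vector (one sample's counts).
#' @param depths integer vector of subsample sizes, each `<= sum(counts)`.
#' @param mode `"analytic"` (default) or `"montecarlo"`.
#' @param reps number of Monte-Carlo subsamples.
#' @param seed seed for Monte-Carlo mode.
#' @return numeric vector of expected richness, one per depth;
#'   non-decreasing in depth.
#' @export
rarefaction_curve <- function(sample_counts, depths,
                              mode = c("analytic", "montecarlo"),
                              reps = 100L, seed = 1L) {
  mode <- match.arg(mode)
  sample_counts <- as.integer(sample_counts)
  if (any(sample_counts < 0)) stop("negative counts")
  total <- sum(sample_counts)
  depths <- as.integer(depths)
  if (any(depths < 1) || any(depths > total))
    stop("each depth must be in [1, total reads]")
  if (mode == "analytic") {
    vapply(depths, function(d)
      unname(suppressWarnings(
        rarefy(matrix(sample_counts, nrow = 1), sample = d))[1]),
      numeric(1))
  } else {
    set.seed(seed)
    x <- matrix(sample_counts, nrow = 1)
    vapply(depths, function(d) {
      mean(vapply(seq_len(reps),
                  function(r) sum(suppressWarnings(rrarefy(x, sample = d)) > 0),
                  numeric(1)))
    }, numeric(1))
  }
}
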