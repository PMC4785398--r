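#' Morisita-Horn ("horn") dissimilarity between two count vectors
#'
#' The abundance-based overlap dissimilarity
#' `d = 1 - 2 * sum(x_i * y_i) / ((sum(x_i^2)/X^2 + sum(y_i^2)/Y^2) * X * Y)`
#' with `X = sum(x)`, `Y = sum(y)` — the "horn" method of classical
#' community-ecology distance functions. It is symmetric, zero iff the two
#' relative-abundance profiles coincide, 1 for disjoint support, and
#' invariant to per-sample depth rescaling, which makes it the natural
#' choice for sequence count data.
#'
#' @param x,y non-negative count vectors of equal length, each with a
#'   positive sum.
#' @return dissimilarity in `[0, 1]`.
#' @export
horn_dissimilarity <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length")
  if (any(x < 0) || any(y < 0)) stop("counts must be non-negative")
  if (sum(x) == 0 || sum(y) == 0) stop("zero-sum vector")
  as.numeric(vegdist(rbind(x, y), method = "horn"))
}

#' Pairwise Horn dissimilarity matrix over samples
#'
#' @param table an [otu_table]; every sample must have positive depth.
#' @param metric currently `"horn"` only.
#' @return symmetric numeric matrix with zero diagonal, sample ids as
#'   dimnames.
#' @export
distance_matrix <- function(table, metric = "horn") {
  metric <- match.arg(metric, "horn")
  depths <- sample_depths(table)
  if (any(depths == 0))
    stop("zero-depth sample(s): ",
         paste(names(depths)[depths == 0], collapse = ", "))
  as.matrix(vegdist(table$counts, method = metric))
}

#' Hierarchical clustering of a distance matrix
#'
#' Standard agglomerative clustering, used for the sample-wise Horn
#' similarity dendrograms.
#'
#' @param d symmetric distance matrix (as from [distance_matrix()]).
#' @param linkage `"average"`, `"complete"` or `"single"`.
#' @return an [stats::hclust] object (merge list with heights).
#' @export
hierarchical_cluster <- function(d,
                                 linkage = c("average", "complete",
                                             "single")) {
  linkage <- match.arg(linkage)
  if (nrow(as.matrix(d)) < 2) stop("need at least 2 samples")
  hclust(as.dist(d), method = linkage)
}

#' Non-metric multidimensional scaling (NMDS)
#'
#' Embeds samples in `k` dimensions so that the rank order of configuration
#' distances matches the input dissimilarities, minimizing Kruskal stress-1
#' with monotone (isotonic) regression, ties treated by Kruskal's primary
#' approach. Runs a metric-scaling start plus up to `n_starts` random
#' restarts and keeps the best configuration. No abundance autotransform is
#' applied (the input is already a dissimilarity).
#'
#' @param d symmetric dissimilarity matrix.
#' @param k embedding dimension (default 2).
#' @param n_starts number of random restarts.
#' @param max_iter maximum iterations per start.
#' @param seed integer seed; the result is deterministic given the seed.
#' @return list of class `nmds_result`: `coordinates` (n x k matrix),
#'   `stress` (Kruskal stress-1 of the returned configuration),
#'   `n_starts_used`, `converged`, `seed`.
#' @export
nmds <- function(d, k = 2L, n_starts = 20L, max_iter = 200L, seed = 1L) {
  dm <- as.matrix(d)
  if (nrow(dm) < k + 1) stop("need at least k + 1 samples")
  set.seed(seed)
  fit <- metaMDS(as.dist(dm), k = k, try = n_starts, trymax = n_starts,
                 autotransform = FALSE, wascores = FALSE, trace = 0,
                 maxit = max_iter)
  conv <- fit$converged
  structure(list(coordinates = fit$points,
                 stress = fit$stress,
                 n_starts_used = as.integer(n_starts),
                 converged = isTRUE(conv) ||
                   (is.numeric(conv) && conv > 0),
                 seed = as.integer(seed)),
            class = "nmds_result")
}

#' @export
print.nmds_result <- function(x, ...) {
  cat(sprintf("NMDS: %d points in %d dims, stress-1 = %.4f (%s)\n",
              nrow(x$coordinates), ncol(x$coordinates), x$stress,
              if (x$converged) "converged" else "no convergent solution"))
  invisible(x)
}

#' Permutational multivariate ANOVA (one factor)
#'
#' Tests whether community dissimilarities differ between groups. The
#' pseudo-F is built from sums of squared distances,
#' `SS_total = sum_{i<j} d_ij^2 / n` and within-group
#' `SS_within = sum_g sum_{i<j in g} d_ij^2 / n_g`, with
#' `F = (SS_between / (k - 1)) / (SS_within / (n - k))`; significance comes
#' from permuting group labels, `p = (1 + #{F_perm >= F_obs}) / (1 + n_perm)`.
#'
#' @param d symmetric distance matrix.
#' @param groups group labels, one per sample (>= 2 groups).
#' @param n_perm number of permutations (default 9999; raise to 1e6 for
#'   publication-grade p-values).
#' @param seed integer seed for the permutations.
#' @return list: `pseudo_F`, `p`, `n_perm`, `seed`.
#' @export
permanova <- function(d, groups, n_perm = 9999L, seed = 1L) {
  dm <- as.matrix(d)
  groups <- as.factor(groups)
  if (length(groups) != nrow(dm))
    stop("one group label per sample required")
  if (nlevels(droplevels(groups)) < 2)
    stop("need at least 2 groups")
  if (any(table(droplevels(groups)) == length(groups)))
    stop("one group absorbs all samples")
  if (n_perm < 1) stop("n_perm must be >= 1")
  set.seed(seed)
  df <- data.frame(g = groups)
  fit <- adonis2(as.dist(dm) ~ g, data = df, permutations = n_perm)
  list(pseudo_F = fit$F[1], p = fit$`Pr(>F)`[1],
       n_perm = as.integer(n_perm), seed = as.integer(seed))
}

#' Pearson co-occurrence matrix of features across samples
#'
#' Correlates relative-abundance profiles of OTUs (or genera, after summing
#' OTU fractions within genus) across samples, as used for taxonomic
#' co-occurrence heatmaps. Features with zero variance give undefined
#' correlations, returned as `NA`.
#'
#' @param table an [otu_table] (taxonomy required for `level = "genus"`).
#' @param level `"otu"` or `"genus"`.
#' @return symmetric correlation matrix with unit diagonal (NA rows/columns
#'   for zero-variance features).
#' @export
cooccurrence <- function(table, level = c("otu", "genus")) {
  level <- match.arg(level)
  if (n_samples(table) < 3) stop("need at least 3 samples")
  depths <- sample_depths(table)
  if (any(depths == 0)) stop("zero-depth sample")
  rel <- table$counts / depths
  if (level == "genus") {
    if (is.null(table$taxonomy)) stop("taxonomy required for genus level")
    gen <- lineage_at_rank(table$taxonomy, "genus")
    gen <- gen[colnames(rel)]
    gen[is.na(gen)] <- "unclassified"
    rel <- t(rowsum(t(rel), group = gen))
  }
  zero_var <- apply(rel, 2, var) == 0
  cc <- suppressWarnings(cor(rel))
  diag(cc) <- 1
  cc[zero_var, ] <- NA_real_
  cc[, zero_var] <- NA_real_
  cc
}
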