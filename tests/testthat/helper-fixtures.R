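# Shared fixtures, all built in code.

# A tiny hand-written table with taxonomy, for I/O and subsetting tests.
toy_table <- function() {
  counts <- matrix(c(10L, 5L, 85L,
                     36L, 24L, 40L,
                     0L, 50L, 50L),
                   nrow = 3, byrow = TRUE,
                   dimnames = list(c("s1", "s2", "s3"),
                                   c("OTU1", "OTU2", "OTU3")))
  tax <- c(
    OTU1 = "Bacteria;Proteobacteria;Gammaproteobacteria;Pseudomonadales;Moraxellaceae;Acinetobacter",
    OTU2 = "Bacteria;Proteobacteria;Alphaproteobacteria;Rickettsiales;Anaplasmataceae;Wolbachia",
    OTU3 = "Bacteria;Firmicutes;Bacilli;Bacillales;Bacillaceae;Bacillus")
  otu_table(counts, taxonomy = tax)
}

# Small fast synthetic dataset for rdCV-level tests: 15 samples in 3 classes,
# fixed moderate depth so rarefaction is unnecessary.
small_dataset <- function(fold_change = 5, n_background = 30L, seed = 101L,
                          class_sizes = c(5L, 5L, 5L), depth = 2000,
                          migrant_specs = list()) {
  generate_dataset(synthetic_config(
    class_sizes = class_sizes,
    n_signature_otus_per_class = 3L,
    signature_fold_change = fold_change,
    n_background_otus = n_background,
    depth_log_mean = log(depth), depth_log_sd = 1e-9,
    migrant_specs = migrant_specs,
    seed = seed))
}

# rdCV configuration scaled for unit tests.
small_config <- function(n_rep = 2L, n_outer = 3L, n_inner = 3L,
                         forest_size = 32L, ...) {
  rdcv_config(n_rep = n_rep, n_outer = n_outer, n_inner = n_inner,
              forest_size = forest_size, ...)
}

# Independent Morisita-Horn oracle: the bare formula.
horn_oracle <- function(x, y) {
  X <- sum(x); Y <- sum(y)
  1 - 2 * sum(x * y) / ((sum(x^2) / X^2 + sum(y^2) / Y^2) * X * Y)
}

# Independent one-factor PERMANOVA pseudo-F from squared distances.
pseudo_f_oracle <- function(dm, groups) {
  n <- nrow(dm)
  groups <- as.factor(groups)
  k <- nlevels(groups)
  ss_total <- sum(dm[upper.tri(dm)]^2) / n
  ss_within <- 0
  for (g in levels(groups)) {
    idx <- which(groups == g)
    sub <- dm[idx, idx, drop = FALSE]
    ss_within <- ss_within + sum(sub[upper.tri(sub)]^2) / length(idx)
  }
  ss_between <- ss_total - ss_within
  (ss_between / (k - 1)) / (ss_within / (n - k))
}
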