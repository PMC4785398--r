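#' Configuration for repeated double cross-validation
#'
#' Controls the rdCV random-forest classifier. The scheme nests an inner
#' cross-validation loop — which tunes the number of OTUs by backward
#' elimination of the 10% least informative OTUs per step, ranked by average
#' importance across inner-segment forests — inside an outer loop that
#' estimates prediction on held-out samples, and repeats the whole double
#' loop with fresh fold splits to build a population of class-probability
#' estimates per observation.
#'
#' @param n_rep number of repetitions of the double CV loop (200 for a full
#'   run; reduce for exploratory work).
#' @param n_outer number of outer CV segments. With ~29 samples, 6 segments
#'   hold out 4-5 samples each.
#' @param n_inner number of inner CV segments used for tuning.
#' @param drop_fraction fraction of the active OTUs eliminated per tuning
#'   step (count rounded up).
#' @param forest_size trees per random forest.
#' @param min_otus smallest OTU set the elimination may reach (>= 2).
#' @param stratified stratify folds by class (recommended: with ~29 samples
#'   in 3 classes, unstratified folds frequently lose a class).
#' @param importance `"permutation"` (out-of-bag accuracy decrease, default)
#'   or `"impurity"` (mean decrease in Gini) for OTU ranking.
#' @param seed master seed; per-repetition seeds are spawned from it, so
#'   results are fully reproducible.
#' @param keep_folds record per-repetition fold assignments in the result
#'   (for audit).
#' @return list of class `rdcv_config`.
#' @export
rdcv_config <- function(n_rep = 200L, n_outer = 6L, n_inner = 5L,
                        drop_fraction = 0.10, forest_size = 128L,
                        min_otus = 2L, stratified = TRUE,
                        importance = c("permutation", "impurity"),
                        seed = 1L, keep_folds = FALSE) {
  importance <- match.arg(importance)
  stopifnot(n_rep >= 1, n_outer >= 2, n_inner >= 2,
            drop_fraction > 0, drop_fraction < 1,
            forest_size >= 1, min_otus >= 2)
  structure(list(n_rep = as.integer(n_rep), n_outer = as.integer(n_outer),
                 n_inner = as.integer(n_inner),
                 drop_fraction = drop_fraction,
                 forest_size = as.integer(forest_size),
                 min_otus = as.integer(min_otus),
                 stratified = isTRUE(stratified),
                 importance = importance,
                 seed = as.integer(seed),
                 keep_folds = isTRUE(keep_folds)),
            class = "rdcv_config")
}

#' Split observations into cross-validation folds
#'
#' Folds are disjoint, cover all observations and differ in size by at most
#' one. Stratified folds preserve class proportions as closely as integer
#' counts allow (members of each class are dealt round-robin, continuing the
#' deal across classes so overall fold sizes stay balanced).
#'
#' @param labels class labels, one per observation.
#' @param n_folds number of folds (`<=` number of observations).
#' @param stratified stratify by class.
#' @param seed integer seed.
#' @return list of `n_folds` integer index vectors.
#' @export
make_folds <- function(labels, n_folds, stratified = TRUE, seed = 1L) {
  n <- length(labels)
  n_folds <- as.integer(n_folds)
  if (n_folds > n) stop("n_folds exceeds number of observations")
  if (n_folds < 2) stop("need at least 2 folds")
  set.seed(seed)
  fold_of <- integer(n)
  if (stratified) {
    pos <- 0L
    for (cl in levels(factor(labels))) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      fold_of[idx] <- ((pos + seq_along(idx) - 1L) %% n_folds) + 1L
      pos <- pos + length(idx)
    }
  } else {
    idx <- sample.int(n)
    fold_of[idx] <- ((seq_len(n) - 1L) %% n_folds) + 1L
  }
  unname(split(seq_len(n), factor(fold_of, levels = seq_len(n_folds))))
}

#' Average OTU rank across inner-segment models
#'
#' Within each model, OTUs are ranked by descending importance (1 = most
#' informative, ties averaged); the returned value is the mean rank across
#' models. This is the ranking that drives backward elimination.
#'
#' @param importance_list list of named importance vectors, all over the
#'   same OTU set.
#' @return named numeric vector of average ranks (lower = more informative).
#' @export
rank_otus <- function(importance_list) {
  if (length(importance_list) < 1) stop("need at least one model")
  ids <- names(importance_list[[1]])
  if (is.null(ids)) stop("importance vectors must be named")
  same <- vapply(importance_list,
                 function(v) identical(sort(names(v)), sort(ids)),
                 logical(1))
  if (!all(same)) stop("models have mismatched OTU sets")
  ranks <- vapply(importance_list,
                  function(v) rank(-v[ids], ties.method = "average"),
                  numeric(length(ids)))
  if (is.null(dim(ranks))) ranks <- matrix(ranks, nrow = 1)
  setNames(rowMeans(ranks), ids)
}

#' One backward-elimination step
#'
#' Removes the `ceiling(drop_fraction * n_active)` worst-average-rank OTUs,
#' never reducing the set below `min_otus`. Rank ties at the cut are broken
#' by the stable order of `active_otus`.
#'
#' @param active_otus character vector of currently active OTU ids.
#' @param avg_rank named average-rank vector (as from [rank_otus()])
#'   covering `active_otus`.
#' @param drop_fraction fraction to drop per step.
#' @param min_otus floor on the set size.
#' @return character vector of retained OTU ids.
#' @export
eliminate_step <- function(active_otus, avg_rank, drop_fraction, min_otus) {
  n_active <- length(active_otus)
  if (n_active <= min_otus) return(active_otus)
  n_drop <- ceiling(drop_fraction * n_active)
  keep_n <- max(min_otus, n_active - n_drop)
  ord <- order(avg_rank[active_otus], seq_len(n_active))
  active_otus[ord][seq_len(keep_n)]
}

# Fit one forest; when xtest is given, held-out predictions are computed in
# the same call (test votes are normalized, i.e. class probabilities) and no
# forest is retained.
.fit_forest <- function(x, y, config, xtest = NULL) {
  y <- factor(y)
  if (any(tabulate(y, nlevels(y)) == 0L)) y <- droplevels(y)
  if (is.null(xtest))
    randomForest(x = x, y = y, ntree = config$forest_size,
                 importance = config$importance == "permutation")
  else
    randomForest(x = x, y = y, xtest = xtest, ntree = config$forest_size,
                 importance = config$importance == "permutation",
                 norm.votes = TRUE, keep.forest = FALSE)
}

.forest_importance <- function(fit, config) {
  imp <- if (config$importance == "permutation")
    importance(fit, type = 1)
  else importance(fit, type = 2)
  setNames(imp[, 1], rownames(imp))
}

#' Inner-loop tuning of the number of OTUs
#'
#' Runs `n_inner`-fold cross-validation inside an outer-training set,
#' iteratively eliminating the least informative OTUs: at each step the
#' current OTU set is scored by total inner-validation misclassifications,
#' OTUs are ranked by average importance across the inner-segment forests,
#' and the worst `drop_fraction` are removed, down to `min_otus`. The
#' selected set is the one minimizing inner misclassifications, ties broken
#' toward fewer OTUs (parsimony).
#'
#' @param x numeric matrix (training samples x OTUs, named columns).
#' @param y class labels for the rows of `x` (>= 2 classes present).
#' @param config an [rdcv_config()].
#' @param seed seed for the inner fold split.
#' @return list: `selected` (character vector of OTU ids) and `curve`
#'   (data.frame with `n_otus` and `misclassifications` per step).
#' @export
inner_tune <- function(x, y, config, seed = 1L) {
  y <- droplevels(factor(y))
  if (nlevels(y) < 2) stop("need >= 2 classes in the training labels")
  folds <- make_folds(y, config$n_inner, config$stratified, seed = seed)
  active <- colnames(x)
  steps <- list()
  repeat {
    imps <- vector("list", length(folds))
    miscl <- 0L
    for (fi in seq_along(folds)) {
      val <- folds[[fi]]
      tr <- setdiff(seq_len(nrow(x)), val)
      fit <- .fit_forest(x[tr, active, drop = FALSE], y[tr], config,
                         xtest = x[val, active, drop = FALSE])
      imps[[fi]] <- .forest_importance(fit, config)
      miscl <- miscl +
        sum(as.character(fit$test$predicted) != as.character(y[val]))
    }
    steps[[length(steps) + 1L]] <-
      list(otus = active, miscl = miscl)
    if (length(active) <= config$min_otus) break
    avg <- rank_otus(imps)
    nxt <- eliminate_step(active, avg, config$drop_fraction,
                          config$min_otus)
    if (length(nxt) == length(active)) break
    active <- nxt
  }
  sizes <- vapply(steps, function(s) length(s$otus), integer(1))
  miscls <- vapply(steps, function(s) s$miscl, integer(1))
  best <- order(miscls, sizes)[1]
  list(selected = steps[[best]]$otus,
       curve = data.frame(n_otus = sizes, misclassifications = miscls))
}

#' Repeated double cross-validated random-forest classification
#'
#' The core predictive procedure: for each repetition, samples are split
#' into `n_outer` outer folds; for each outer fold, [inner_tune()] selects
#' the most informative OTU set on the outer-training portion alone, a
#' random forest is fitted on that portion restricted to the selected OTUs,
#' and class probabilities are recorded for the held-out fold. Each
#' observation is therefore predicted exactly once per repetition by a model
#' that never saw it. Repetitions (fresh folds each time) yield a
#' population of classification probabilities per observation; the consensus
#' class is the argmax of the repetition-mean probability.
#'
#' @param table an [otu_table] (after depth filtering/rarefaction).
#' @param labels class labels (e.g. village of capture), one per sample.
#' @param config an [rdcv_config()].
#' @return object of class `rdcv_result`: `prob` (sample x class x
#'   repetition probability array), `consensus_prob`, `consensus_class`,
#'   `n_misclassified`, `selected_n_otus` (repetition x outer-fold matrix),
#'   `importance_rank` (per-OTU average rank over all outer models; OTUs an
#'   outer model did not select share the tied average of its trailing rank
#'   positions), `labels`, `config`, and `folds` (per-repetition fold
#'   assignments, if `keep_folds`).
#' @export
run_rdcv <- function(table, labels, config = rdcv_config()) {
  x <- table$counts
  storage.mode(x) <- "double"
  labels <- factor(as.character(labels))
  if (length(labels) != nrow(x)) stop("one label per sample required")
  if (nlevels(labels) < 2) stop("need >= 2 classes")
  if (config$stratified && config$n_outer > min(table(labels)))
    stop("stratified folds require n_outer <= smallest class size")
  n <- nrow(x)
  p <- ncol(x)
  classes <- levels(labels)  # lexicographic order
  k <- length(classes)

  set.seed(config$seed)
  rep_seeds <- sample.int(2147483000L, config$n_rep)

  prob <- array(NA_real_, dim = c(n, k, config$n_rep),
                dimnames = list(rownames(x), classes, NULL))
  selected_n <- matrix(NA_integer_, config$n_rep, config$n_outer)
  rank_accum <- setNames(numeric(p), colnames(x))
  n_outer_models <- 0L
  folds_log <- if (config$keep_folds) vector("list", config$n_rep)

  for (r in seq_len(config$n_rep)) {
    outer_folds <- make_folds(labels, config$n_outer, config$stratified,
                              seed = rep_seeds[r])
    if (config$keep_folds) folds_log[[r]] <- outer_folds
    for (oi in seq_along(outer_folds)) {
      test <- outer_folds[[oi]]
      train <- setdiff(seq_len(n), test)
      tune <- inner_tune(x[train, , drop = FALSE], labels[train], config,
                         seed = rep_seeds[r] + oi)
      sel <- tune$selected
      fit <- .fit_forest(x[train, sel, drop = FALSE], labels[train], config,
                         xtest = x[test, sel, drop = FALSE])
      pr <- fit$test$votes
      pm <- matrix(0, length(test), k,
                   dimnames = list(rownames(x)[test], classes))
      pm[, colnames(pr)] <- pr
      prob[test, , r] <- pm
      selected_n[r, oi] <- length(sel)
      imp <- .forest_importance(fit, config)
      m <- length(sel)
      full <- setNames(rep(m + (p - m + 1) / 2, p), colnames(x))
      full[sel] <- rank(-imp, ties.method = "average")
      rank_accum <- rank_accum + full
      n_outer_models <- n_outer_models + 1L
    }
  }
  stopifnot(!anyNA(prob))  # every observation predicted once per repetition

  consensus_prob <- apply(prob, c(1, 2), mean)
  consensus_class <- classes[apply(consensus_prob, 1, which.max)]
  names(consensus_class) <- rownames(x)
  structure(list(prob = prob,
                 consensus_prob = consensus_prob,
                 consensus_class = consensus_class,
                 n_misclassified =
                   sum(consensus_class != as.character(labels)),
                 selected_n_otus = selected_n,
                 importance_rank = rank_accum / n_outer_models,
                 labels = setNames(as.character(labels), rownames(x)),
                 config = config,
                 folds = folds_log),
            class = "rdcv_result")
}

#' @export
print.rdcv_result <- function(x, ...) {
  n <- length(x$consensus_class)
  cat(sprintf(
    "rdCV result: %d samples, %d classes, %d repetitions\n",
    n, ncol(x$consensus_prob), dim(x$prob)[3]))
  cat(sprintf("consensus misclassifications: %d / %d (accuracy %.1f%%)\n",
              x$n_misclassified, n, 100 * (1 - x$n_misclassified / n)))
  invisible(x)
}

#' Aggregate OTU importance ranks to genus level
#'
#' Summarizes an rdCV result's per-OTU average ranks by genus (the best,
#' i.e. smallest, OTU rank within each genus), giving the ordered list of
#' marker genera driving the classification.
#'
#' @param result an `rdcv_result`.
#' @param taxonomy named lineage vector covering the OTUs in the result.
#' @return data.frame with `genus`, `best_rank`, `n_otus`, ordered by
#'   `best_rank` (ties by genus name).
#' @export
importance_summary <- function(result, taxonomy) {
  ranks <- result$importance_rank
  miss <- setdiff(names(ranks), names(taxonomy))
  if (length(miss)) stop("taxonomy missing for OTUs: ",
                         paste(utils::head(miss, 5), collapse = ", "))
  gen <- lineage_at_rank(taxonomy[names(ranks)], "genus")
  gen[is.na(gen)] <- "unclassified"
  best <- tapply(ranks, gen, min)
  cnt <- tapply(ranks, gen, length)
  df <- data.frame(genus = names(best), best_rank = as.numeric(best),
                   n_otus = as.integer(cnt), stringsAsFactors = FALSE)
  df <- df[order(df$best_rank, df$genus), ]
  rownames(df) <- NULL
  df
}
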