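test_that("folds partition the observations with balanced sizes", {
  labels <- rep(c("a", "b", "c"), each = 2)
  f <- make_folds(labels, 3, stratified = FALSE, seed = 1)
  expect_equal(lengths(f), rep(2L, 3))
  expect_equal(sort(unlist(f)), 1:6)

  labs <- rep(c("a", "b"), each = 4)
  fs <- make_folds(labs, 2, stratified = TRUE, seed = 2)
  for (fold in fs) {
    expect_equal(length(fold), 4L)
    expect_equal(sum(labs[fold] == "a"), 2L)  # 2 + 2 per fold
  }

  # partition property over many draws
  labs2 <- rep(c("x", "y", "z"), times = c(10, 10, 9))
  for (seed in 1:10) {
    f2 <- make_folds(labs2, 6, stratified = TRUE, seed = seed)
    expect_equal(sort(unlist(f2)), 1:29)
    expect_lte(diff(range(lengths(f2))), 1L)
  }
  expect_error(make_folds(c("a", "b"), 3), "exceeds")
  expect_identical(make_folds(labs2, 6, seed = 5),
                   make_folds(labs2, 6, seed = 5))
})

test_that("rank_otus averages descending-importance ranks", {
  one <- list(c(a = 0.5, b = 0.2, c = 0.3))
  expect_equal(rank_otus(one), c(a = 1, b = 3, c = 2))

  rev2 <- list(c(a = 1, b = 2), c(a = 2, b = 1))
  expect_equal(rank_otus(rev2), c(a = 1.5, b = 1.5))

  set.seed(12)
  three <- lapply(1:3, function(i) setNames(runif(6), letters[1:6]))
  brute <- colMeans(do.call(rbind, lapply(three, function(v)
    rank(-v)[letters[1:6]])))
  expect_equal(rank_otus(three), brute)

  expect_error(rank_otus(list(c(a = 1), c(b = 1))), "mismatched")
})

test_that("eliminate_step drops the ceiling-fraction worst OTUs", {
  ids100 <- sprintf("o%03d", 1:100)
  rk <- setNames(seq_along(ids100), ids100)  # o001 best ... o100 worst
  kept <- eliminate_step(ids100, rk, 0.10, 2)
  expect_equal(length(kept), 90L)
  expect_equal(kept, ids100[1:90])

  # floor rule: cannot go below min_otus
  expect_equal(length(eliminate_step(c("a", "b", "c"),
                                     c(a = 1, b = 2, c = 3), 0.10, 2)), 2L)

  # 10 OTUs at 10%: exactly the single worst-ranked OTU is removed
  ids10 <- letters[1:10]
  rk10 <- setNames(sample(10), ids10)
  kept10 <- eliminate_step(ids10, rk10, 0.10, 2)
  expect_equal(setdiff(ids10, kept10), ids10[which.max(rk10)])

  # ties at the cut break by stable input order
  tied <- setNames(rep(1, 4), c("w", "x", "y", "z"))
  expect_equal(eliminate_step(c("w", "x", "y", "z"), tied, 0.25, 2),
               c("w", "x", "y"))
})

test_that("inner tuning finds a separating OTU and favors parsimony", {
  set.seed(31)
  n <- 18
  y <- factor(rep(c("A", "B"), each = n / 2))
  x <- matrix(rpois(n * 12, 20), n, 12,
              dimnames = list(NULL, sprintf("noise%02d", 1:12)))
  x <- cbind(x, key = c(rpois(n / 2, 5), rpois(n / 2, 60)))
  res <- inner_tune(x, y, small_config(seed = 1), seed = 5)
  expect_true("key" %in% res$selected)
  expect_equal(min(res$curve$misclassifications), 0)
  # curve covers the elimination path down to min_otus
  expect_equal(res$curve$n_otus[1], 13L)
  expect_equal(res$curve$n_otus[nrow(res$curve)], 2L)

  # two-point argmin when only one elimination step is possible
  small <- x[, c(1, 2, 13)]
  res2 <- inner_tune(small, y, small_config(seed = 1), seed = 5)
  expect_equal(nrow(res2$curve), 2L)
  best <- which.min(res2$curve$misclassifications)
  expect_equal(length(res2$selected), res2$curve$n_otus[best])
})

test_that("run_rdcv yields valid, reproducible probability populations", {
  dat <- small_dataset()
  cfg <- small_config(seed = 42, keep_folds = TRUE)
  res <- run_rdcv(dat$table, dat$metadata$location, cfg)

  expect_equal(dim(res$prob), c(15L, 3L, 2L))
  sums <- apply(res$prob, c(1, 3), sum)
  expect_equal(unname(sums), matrix(1, 15, 2), tolerance = 1e-9)
  expect_true(all(res$prob >= 0 & res$prob <= 1))
  expect_equal(res$n_misclassified,
               sum(res$consensus_class != dat$metadata$location))
  expect_equal(res$consensus_prob,
               apply(res$prob, c(1, 2), mean))

  # determinism: identical config + seed -> identical result
  res_b <- run_rdcv(dat$table, dat$metadata$location, cfg)
  expect_identical(res$prob, res_b$prob)
  expect_identical(res$importance_rank, res_b$importance_rank)

  # information isolation: outer folds partition the samples each repetition,
  # so the model predicting sample i was trained without sample i
  for (r in seq_along(res$folds))
    expect_equal(sort(unlist(res$folds[[r]])), 1:15)

  # strong signature signal is recovered
  expect_lte(res$n_misclassified, 2L)
})

test_that("a strong migrant is classified to its source village", {
  dat <- small_dataset(
    fold_change = 8, seed = 77,
    migrant_specs = list(list(sample_index = 1, source_class = "VK5",
                              weight = 0.9)))
  res <- run_rdcv(dat$table, dat$metadata$location,
                  small_config(n_rep = 3L, seed = 9))
  expect_equal(unname(res$consensus_class[1]), "VK5")
})

test_that("permuted-label misclassifications sit at the predicted null mean
           regardless of signal strength", {
  mean_null <- function(fold_change) {
    dat <- small_dataset(fold_change = fold_change, n_background = 15L,
                         seed = 55)
    set.seed(90)
    counts <- vapply(1:12, function(i) {
      perm <- sample(15)
      run_rdcv(dat$table, dat$metadata$location[perm],
               small_config(n_rep = 1L, seed = 100 + i))$n_misclassified
    }, numeric(1))
    counts
  }
  c1 <- mean_null(1)
  c5 <- mean_null(5)
  pred <- predicted_h0_mean(c(5, 5, 5))  # 10
  se <- sd(c(c1, c5)) / sqrt(12)
  expect_lt(abs(mean(c1) - pred), 4 * se + 1)
  expect_lt(abs(mean(c5) - pred), 4 * se + 1)
  # null behavior does not depend on the (unused) signature fold change
  expect_lt(abs(mean(c1) - mean(c5)),
            4 * sd(c(c1, c5)) * sqrt(2 / 12) + 1)
})

test_that("importance aggregates to genus by best OTU rank", {
  fake <- structure(list(importance_rank = c(
    OTU_a1 = 3, OTU_a2 = 1.5, OTU_b1 = 2, OTU_c1 = 7)),
    class = "rdcv_result")
  tax <- c(OTU_a1 = "B;P;C;O;F;GenA", OTU_a2 = "B;P;C;O;F;GenA",
           OTU_b1 = "B;P;C;O;F;GenB", OTU_c1 = "B;P;C;O;F;GenC")
  s <- importance_summary(fake, tax)
  expect_equal(s$genus, c("GenA", "GenB", "GenC"))
  expect_equal(s$best_rank, c(1.5, 2, 7))
  expect_equal(s$n_otus, c(2L, 1L, 1L))
  # brute-force group-by-min agreement
  brute <- tapply(fake$importance_rank,
                  sub(".*;", "", tax[names(fake$importance_rank)]), min)
  expect_equal(s$best_rank, as.vector(brute[s$genus]))

  # signature genera outrank background genera under strong signal
  dat <- small_dataset(seed = 13)
  res <- run_rdcv(dat$table, dat$metadata$location,
                  small_config(n_rep = 3L, seed = 3))
  imp <- importance_summary(res, dat$table$taxonomy)
  sig_genera <- c("Massilia-like", "Wolbachia-like", "Shewanella-like")
  sig_rank <- max(imp$best_rank[imp$genus %in% sig_genera])
  bg_rank <- min(imp$best_rank[!(imp$genus %in% sig_genera)])
  expect_lt(sig_rank, bg_rank)
})

test_that("config preconditions are enforced", {
  dat <- small_dataset()
  expect_error(run_rdcv(dat$table, dat$metadata$location,
                        small_config(n_outer = 6L)),
               "smallest class")
  expect_error(run_rdcv(dat$table, rep("one", 15), small_config()),
               "2 classes")
  expect_error(rdcv_config(drop_fraction = 0), "drop_fraction")
  expect_error(rdcv_config(min_otus = 1), "min_otus")
})
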