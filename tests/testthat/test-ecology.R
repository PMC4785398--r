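test_that("Horn dissimilarity satisfies its identities and formula", {
  expect_equal(horn_dissimilarity(c(3, 1, 4), c(3, 1, 4)), 0)
  expect_equal(horn_dissimilarity(c(3, 0), c(0, 7)), 1)
  # hand evaluation: x=(1,1), y=(1,0) -> 1 - 2/((1/2 + 1)*2) = 1/3
  expect_equal(horn_dissimilarity(c(1, 1), c(1, 0)), 1 / 3)

  set.seed(5)
  for (i in 1:20) {
    x <- rpois(12, 8); y <- rpois(12, 8)
    x[1] <- x[1] + 1; y[2] <- y[2] + 1  # guarantee positive sums
    expect_equal(horn_dissimilarity(x, y), horn_oracle(x, y),
                 tolerance = 1e-12)
    expect_equal(horn_dissimilarity(x, y), horn_dissimilarity(y, x))
    # invariance to per-sample depth rescaling
    expect_equal(horn_dissimilarity(x, 7 * y), horn_dissimilarity(x, y),
                 tolerance = 1e-12)
    d <- horn_dissimilarity(x, y)
    expect_gte(d, 0); expect_lte(d, 1)
  }
  expect_error(horn_dissimilarity(c(0, 0), c(1, 2)), "zero-sum")
  expect_error(horn_dissimilarity(c(1, 2, 3), c(1, 2)), "length")
})

test_that("distance_matrix is the symmetric pairwise Horn matrix", {
  dat <- small_dataset(depth = 800)
  d <- distance_matrix(dat$table)
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, nrow(d)))
  # brute-force loop oracle
  cts <- dat$table$counts
  for (i in c(1, 4, 9)) for (j in c(2, 7, 15))
    expect_equal(d[i, j], horn_oracle(cts[i, ], cts[j, ]),
                 tolerance = 1e-12)

  dup_m <- rbind(a = c(5L, 3L), b = c(5L, 3L), c = c(1L, 9L))
  colnames(dup_m) <- c("o1", "o2")
  expect_equal(distance_matrix(otu_table(dup_m))["a", "b"], 0)

  zz <- otu_table(matrix(c(1L, 0L, 2L, 0L), 2, 2,
                         dimnames = list(c("ok", "empty"), c("o1", "o2"))))
  expect_error(distance_matrix(zz), "empty")
})

test_that("hierarchical clustering matches a brute-force agglomeration", {
  two <- matrix(c(0, 0.4, 0.4, 0), 2, 2, dimnames = list(c("a", "b"),
                                                         c("a", "b")))
  h2 <- hierarchical_cluster(two)
  expect_equal(h2$height, 0.4)

  # three points, one tight pair merges first
  p <- c(0, 5, 0.1)
  d3 <- as.matrix(dist(p)); dimnames(d3) <- list(letters[1:3], letters[1:3])
  h3 <- hierarchical_cluster(d3, "average")
  expect_equal(sort(h3$merge[1, ]), c(-3, -1))  # points 1 and 3

  # 6-point random matrix vs naive UPGMA oracle
  set.seed(8)
  pts <- matrix(rnorm(12), 6, 2)
  dm <- as.matrix(dist(pts))
  oracle_heights <- local({
    clusters <- as.list(seq_len(6))
    heights <- numeric(0)
    while (length(clusters) > 1) {
      best <- c(Inf, NA, NA)
      for (i in seq_along(clusters)) for (j in seq_len(i - 1)) {
        h <- mean(dm[clusters[[i]], clusters[[j]]])
        if (h < best[1]) best <- c(h, j, i)
      }
      heights <- c(heights, best[1])
      clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
      clusters[[best[3]]] <- NULL
    }
    heights
  })
  expect_equal(hierarchical_cluster(dm, "average")$height, oracle_heights,
               tolerance = 1e-12)
  expect_error(hierarchical_cluster(matrix(0, 1, 1)), "2 samples")
})

test_that("NMDS recovers exactly embeddable configurations", {
  set.seed(21)
  pts <- matrix(rnorm(16), 8, 2)
  dm <- as.matrix(dist(pts))
  dimnames(dm) <- list(letters[1:8], letters[1:8])
  fit <- nmds(dm, k = 2, n_starts = 10, seed = 3)
  expect_lt(fit$stress, 0.01)
  expect_equal(dim(fit$coordinates), c(8L, 2L))
  # determinism
  fit2 <- nmds(dm, k = 2, n_starts = 10, seed = 3)
  expect_identical(fit$coordinates, fit2$coordinates)
})

test_that("NMDS stress is near the many-restart optimum on a toy matrix", {
  set.seed(99)
  dm <- as.matrix(dist(matrix(rnorm(15), 5, 3)))  # 3-D points into 2-D
  dimnames(dm) <- list(letters[1:5], letters[1:5])
  fit <- nmds(dm, k = 2, n_starts = 20, seed = 1)
  ref <- min(vapply(1:60, function(i) {
    set.seed(2000 + i)
    y0 <- matrix(rnorm(10), 5, 2)
    vegan::monoMDS(as.dist(dm), y = y0, k = 2)$stress
  }, numeric(1)))
  expect_lt(fit$stress, ref + 1e-3)
})

test_that("PERMANOVA p-values match exhaustive enumeration at n = 6", {
  set.seed(17)
  pts <- c(rnorm(3, 0), rnorm(3, 1.2))
  dm <- as.matrix(dist(pts))
  dimnames(dm) <- list(paste0("s", 1:6), paste0("s", 1:6))
  groups <- rep(c("A", "B"), each = 3)

  res <- permanova(dm, groups, n_perm = 999L, seed = 4)
  expect_equal(res$pseudo_F, pseudo_f_oracle(dm, groups), tolerance = 1e-9)

  combs <- utils::combn(6, 3)
  f_all <- apply(combs, 2, function(idx) {
    g <- rep("B", 6); g[idx] <- "A"
    pseudo_f_oracle(dm, g)
  })
  p_exact <- mean(f_all >= res$pseudo_F - 1e-12)
  mc_se <- sqrt(p_exact * (1 - p_exact) / 999)
  expect_lt(abs(res$p - p_exact), 3 * mc_se + 2 / 1000)

  # relabeling group names leaves the test invariant
  relabeled <- permanova(dm, ifelse(groups == "A", "grp2", "grp1"),
                         n_perm = 999L, seed = 4)
  expect_equal(relabeled$p, res$p)
  expect_equal(relabeled$pseudo_F, res$pseudo_F)
})

test_that("clearly separated clusters reach the minimal p-value", {
  set.seed(2)
  pts <- rbind(matrix(rnorm(10, 0, 0.01), 5, 2),
               matrix(rnorm(10, 50, 0.01), 5, 2))
  dm <- as.matrix(dist(pts))
  dimnames(dm) <- list(paste0("s", 1:10), paste0("s", 1:10))
  res <- permanova(dm, rep(c("x", "y"), each = 5), n_perm = 999L, seed = 1)
  expect_equal(res$p, 1 / 1000)
})

test_that("co-occurrence correlations match the textbook formula", {
  cts <- matrix(c(10L, 20L, 30L,
                  20L, 40L, 60L,
                  5L, 10L, 2L,
                  65L, 30L, 8L), 3, 4,
                dimnames = list(c("s1", "s2", "s3"),
                                c("dup1", "dup2", "o3", "o4")))
  tab <- otu_table(cts)
  cc <- cooccurrence(tab)
  expect_equal(cc["dup1", "dup2"], 1)  # proportional features
  expect_equal(diag(cc), setNames(rep(1, 4), colnames(cts)))

  rel <- cts / rowSums(cts)
  man <- sum((rel[, 3] - mean(rel[, 3])) * (rel[, 4] - mean(rel[, 4]))) /
    (sqrt(sum((rel[, 3] - mean(rel[, 3]))^2)) *
       sqrt(sum((rel[, 4] - mean(rel[, 4]))^2)))
  expect_equal(cc["o3", "o4"], man, tolerance = 1e-12)

  # two-OTU table at fixed depth: complements correlate at exactly -1
  comp <- otu_table(matrix(c(10L, 40L, 25L, 90L, 60L, 75L), 3, 2,
                           dimnames = list(paste0("s", 1:3), c("a", "b"))))
  expect_equal(cooccurrence(comp)["a", "b"], -1)

  # zero-variance feature is flagged as missing
  const <- otu_table(matrix(c(10L, 10L, 10L, 1L, 5L, 9L, 9L, 5L, 1L), 3, 3,
                            dimnames = list(paste0("s", 1:3),
                                            c("flat", "up", "dn"))))
  ccz <- cooccurrence(const)
  expect_true(all(is.na(ccz["flat", ])))
  expect_equal(ccz["up", "dn"], -1)
})

test_that("genus-level co-occurrence aggregates OTU fractions", {
  tab <- toy_table()
  cc <- cooccurrence(tab, level = "genus")
  expect_equal(sort(colnames(cc)),
               c("Acinetobacter", "Bacillus", "Wolbachia"))
  expect_equal(diag(cc), setNames(rep(1, 3), colnames(cc)))
})
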