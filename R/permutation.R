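#' Expected misclassifications under the permutation null
#'
#' When class labels are permuted, predictions carry no label information
#' and the expected number of misclassified observations is
#' `n - sum(n_k^2) / n` with `n = sum(n_k)`; for K balanced classes this is
#' `(1 - 1/K) * n`. For 29 observations in three (near-)balanced classes
#' this gives 2/3 * 29 ~= 19.3 — the benchmark the estimated H0 mean of a
#' valid, non-overfitted model should reproduce.
#'
#' @param class_sizes positive integer vector of class sizes.
#' @return expected misclassification count (numeric).
#' @export
predicted_h0_mean <- function(class_sizes) {
  if (length(class_sizes) < 1) stop("empty class_sizes")
  if (any(class_sizes <= 0)) stop("class sizes must be positive")
  n <- sum(class_sizes)
  n - sum(class_sizes^2) / n
}

#' Build the permuted-label H0 misclassification population
#'
#' Fits `n_models` rdCV models in which the class labels are randomly drawn
#' without replacement (i.e. permuted) and records each model's consensus
#' misclassification count. The resulting population is the empirical null
#' against which the real model's misclassification count is judged; its
#' mean should sit at [predicted_h0_mean()] when the procedure does not
#' overfit. Null models run with a reduced repetition count (`null_n_rep`)
#' by default: the null misclassification mean does not depend on the number
#' of repetitions, and full-scale repetitions across hundreds of null models
#' are unnecessary.
#'
#' @param table an [otu_table].
#' @param labels true class labels, one per sample.
#' @param config an [rdcv_config()] describing the model under test.
#' @param n_models number of permuted-label models (400 for a full run).
#' @param null_n_rep repetitions per null model (default 1; set to
#'   `config$n_rep` for fully paper-scale nulls).
#' @param seed integer seed for permutations and model seeds.
#' @return object of class `h0_population`: `counts`, `n_models`, `mean`,
#'   `sd`, `df` (= n_models - 1), `skewness`, `excess_kurtosis` (moment
#'   estimators; shape diagnostics for the t-distribution assumption).
#' @export
build_h0 <- function(table, labels, config = rdcv_config(),
                     n_models = 400L, null_n_rep = 1L, seed = 1L) {
  if (n_models < 2) stop("n_models must be >= 2")
  n <- n_samples(table)
  if (length(labels) != n) stop("one label per sample required")
  set.seed(seed)
  perms <- lapply(seq_len(n_models), function(i) sample.int(n))
  model_seeds <- sample.int(2147483000L, n_models)
  null_config <- config
  null_config$n_rep <- as.integer(null_n_rep)
  null_config$keep_folds <- FALSE
  counts <- vapply(seq_len(n_models), function(m) {
    null_config$seed <- model_seeds[m]
    run_rdcv(table, labels[perms[[m]]], null_config)$n_misclassified
  }, numeric(1))
  mu <- mean(counts)
  s <- sd(counts)
  z <- (counts - mu) / s
  structure(list(counts = counts,
                 n_models = as.integer(n_models),
                 mean = mu, sd = s,
                 df = as.integer(n_models) - 1L,
                 skewness = mean(z^3),
                 excess_kurtosis = mean(z^4) - 3,
                 seed = as.integer(seed)),
            class = "h0_population")
}

#' @export
print.h0_population <- function(x, ...) {
  cat(sprintf(
    "H0 population: %d permuted-label models, mean %.2f, sd %.2f\n",
    x$n_models, x$mean, x$sd))
  cat(sprintf("shape: skewness %.2f, excess kurtosis %.2f\n",
              x$skewness, x$excess_kurtosis))
  invisible(x)
}

#' Model-validity p-value against the H0 population
#'
#' Lower-tail cumulative probability of the observed misclassification count
#' within a t-distributed H0 population: the population is fitted by its
#' sample mean and SD (location-scale) with `n_models - 1` degrees of
#' freedom, and `p = P(T <= (observed - mean) / sd)`. Few misclassifications
#' relative to the null give a small p, i.e. a valid model.
#'
#' @param observed observed misclassification count of the real-label model.
#' @param h0 an `h0_population` from [build_h0()].
#' @return p-value in (0, 1), monotone increasing in `observed`.
#' @export
h0_pvalue <- function(observed, h0) {
  stopifnot(inherits(h0, "h0_population"))
  if (!is.finite(h0$sd) || h0$sd <= 0)
    stop("degenerate null: sd of the H0 population is zero")
  pt((observed - h0$mean) / h0$sd, df = h0$df)
}
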