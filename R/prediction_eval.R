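# Evaluation of predicted strength classes against measured repression:
# accuracy-maximizing ordinal binning, confusion matrix, and permutation /
# bootstrap null models with two-tailed p-values.

#' Bin continuous repression values into ordinal classes
#'
#' Class k covers the half-open interval `[t_{k-1}, t_k)` with infinite end
#' caps, so a value exactly at a threshold falls in the upper class and
#' higher repression maps to a higher class.
#'
#' @param values Numeric vector (repression scale).
#' @param thresholds Three strictly increasing reals.
#' @return Integer classes in 1..4.
#' @export
bin_observed <- function(values, thresholds) {
  if (length(thresholds) != 3 || any(diff(thresholds) <= 0)) {
    stop("thresholds must be 3 strictly increasing values", call. = FALSE)
  }
  1L + findInterval(values, thresholds)
}

#' Accuracy-maximizing ordinal thresholds
#'
#' Finds three thresholds on the observed repression scale that maximize
#' the accuracy of binning the values and matching the predicted ordinal
#' classes. The search is exhaustive over cut positions between consecutive
#' sorted distinct values (plus the two outer caps), which contains a global
#' optimum because accuracy only changes when a threshold crosses a data
#' value. Ties break toward the lexicographically smallest cut triple.
#' Degenerate solutions with empty classes (two or three cuts in the same
#' gap) are allowed; the returned thresholds are then spread within the gap
#' so they remain strictly increasing.
#'
#' @param values Numeric observed repression values (>= 4, >= 4 distinct).
#' @param predicted Integer predicted classes in 1..4.
#' @return List with `thresholds` (length 3), `accuracy`, and `cuts`
#'   (internal cut counts, for reference).
#' @export
optimize_thresholds <- function(values, predicted) {
  stopifnot(length(values) == length(predicted))
  if (length(values) < 4) stop("need at least 4 values", call. = FALSE)
  if (!all(predicted %in% 1:4)) stop("predicted classes must be in 1..4",
                                     call. = FALSE)
  d <- sort(unique(values))
  m <- length(d)
  if (m < 4) stop("need at least 4 distinct values", call. = FALSE)
  r <- match(values, d)  # distinct-value rank of each observation
  # cum[k + 1, c] = number of observations with rank <= k and predicted class c
  counts <- table(factor(r, levels = seq_len(m)),
                  factor(predicted, levels = 1:4))
  cum <- rbind(0, apply(counts, 2, cumsum))
  # enumerate k1 <= k2 <= k3 in 0..m; accuracy decomposes over the 4 bins
  grid <- expand.grid(k3 = 0:m, k2 = 0:m, k1 = 0:m)
  grid <- grid[grid$k1 <= grid$k2 & grid$k2 <= grid$k3, , drop = FALSE]
  hits <- cum[grid$k1 + 1L, 1L] +
    (cum[grid$k2 + 1L, 2L] - cum[grid$k1 + 1L, 2L]) +
    (cum[grid$k3 + 1L, 3L] - cum[grid$k2 + 1L, 3L]) +
    (cum[m + 1L, 4L] - cum[grid$k3 + 1L, 4L])
  best <- max(hits)
  cand <- grid[hits == best, , drop = FALSE]
  cand <- cand[order(cand$k1, cand$k2, cand$k3), , drop = FALSE]
  cuts <- as.integer(unlist(cand[1L, c("k1", "k2", "k3")]))
  list(thresholds = cuts_to_thresholds(cuts, d),
       accuracy = best / length(values), cuts = cuts)
}

# Map cut counts (number of distinct values strictly below the threshold)
# to strictly increasing real thresholds; cuts sharing a gap are spread
# evenly within it.
cuts_to_thresholds <- function(cuts, d) {
  m <- length(d)
  gap_bounds <- function(k) {
    lo <- if (k == 0) d[1] - 2 else d[k]
    hi <- if (k == m) d[m] + 2 else d[k + 1]
    c(lo, hi)
  }
  th <- numeric(3)
  for (k in unique(cuts)) {
    idx <- which(cuts == k)
    b <- gap_bounds(k)
    th[idx] <- b[1] + (b[2] - b[1]) * seq_along(idx) / (length(idx) + 1)
  }
  th
}

#' Confusion matrix and accuracy
#'
#' @param predicted,observed Integer class vectors in 1..4, equal length.
#' @return List with `confusion` (4x4 integer matrix, rows = predicted,
#'   columns = observed) and `accuracy` (normalized trace).
#' @export
confusion_and_accuracy <- function(predicted, observed) {
  if (length(predicted) != length(observed)) {
    stop("predicted and observed must have equal length", call. = FALSE)
  }
  stopifnot(all(predicted %in% 1:4), all(observed %in% 1:4))
  cm <- table(predicted = factor(predicted, levels = 1:4),
              observed = factor(observed, levels = 1:4))
  cm <- unclass(cm)
  storage.mode(cm) <- "integer"
  list(confusion = cm, accuracy = sum(diag(cm)) / length(predicted))
}

# Shared summary of a null accuracy distribution against the real accuracy.
summarize_null <- function(null_acc, real_acc, seed) {
  N <- length(null_acc)
  k_ge <- sum(null_acc >= real_acc)
  k_le <- sum(null_acc <= real_acc)
  structure(
    list(
      real_accuracy = real_acc,
      null_accuracies = null_acc,
      null_mean = mean(null_acc),
      null_sd = stats::sd(null_acc),
      percentile_outperformed = 100 * mean(null_acc < real_acc),
      p_two_tailed_empirical = min(1, 2 * min((k_ge + 1) / (N + 1),
                                              (k_le + 1) / (N + 1))),
      p_two_tailed_normal = 2 * stats::pnorm(
        -abs((real_acc - mean(null_acc)) / stats::sd(null_acc))),
      n_iterations = N,
      seed = as.integer(seed)
    ),
    class = "null_eval"
  )
}

#' Permutation null for prediction accuracy
#'
#' Shuffles the observed class labels uniformly `n_perm` times and
#' recomputes the accuracy of the fixed predictions against each shuffle
#' (the observed binning, hence the fitted thresholds, is held fixed).
#' Reports the null mean and SD, the percentage of null runs the real
#' accuracy outperforms, an empirical two-tailed p-value with the +1
#' correction, and a normal-approximation two-tailed p-value.
#'
#' @param predicted,observed Integer class vectors in 1..4 (length >= 4).
#' @param n_perm Number of permutations (>= 1).
#' @param seed Integer seed.
#' @return Object of class `null_eval`.
#' @export
permutation_null <- function(predicted, observed, n_perm = 1000L, seed = 1L) {
  stopifnot(length(predicted) == length(observed))
  if (length(observed) < 4) stop("need n >= 4", call. = FALSE)
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  if (n_perm < 100) warning("fewer than 100 permutations: p-values have low ",
                            "resolution", call. = FALSE)
  real <- mean(predicted == observed)
  null_acc <- with_seed(seed, {
    vapply(seq_len(n_perm),
           function(i) mean(predicted == sample(observed)), numeric(1))
  })
  summarize_null(null_acc, real, seed)
}

#' Bootstrap random-guessing null for prediction accuracy
#'
#' Each run draws n independent uniform guesses over the four classes and
#' scores them against the fixed observed classes, so the expected null
#' accuracy is 0.25 whatever the observed class distribution. Summaries are
#' as in [permutation_null()], comparing against the real accuracy of
#' `predicted`.
#'
#' @param predicted,observed Integer class vectors in 1..4.
#' @param n_runs Number of bootstrap runs (>= 1).
#' @param seed Integer seed.
#' @return Object of class `null_eval`.
#' @export
bootstrap_random_null <- function(predicted, observed, n_runs = 1000L,
                                  seed = 1L) {
  stopifnot(length(predicted) == length(observed))
  if (n_runs < 1) stop("n_runs must be >= 1", call. = FALSE)
  n <- length(observed)
  real <- mean(predicted == observed)
  null_acc <- with_seed(seed, {
    vapply(seq_len(n_runs),
           function(i) mean(sample.int(4L, n, replace = TRUE) == observed),
           numeric(1))
  })
  summarize_null(null_acc, real, seed)
}

#' Full evaluation of predicted strength classes
#'
#' Fits accuracy-maximizing thresholds on the observed repression values,
#' bins them, builds the confusion matrix, and runs both null models with
#' the binning held fixed.
#'
#' @param predicted Integer predicted classes in 1..4 (or an ordered factor,
#'   converted by level order).
#' @param observed_repression Numeric measured repression (e.g.
#'   `1 - relative_gfp`).
#' @param n_perm,n_boot Iterations for the two null models.
#' @param seed Integer seed (fanned out to the two nulls).
#' @return Object of class `synear_eval`: thresholds, confusion matrix,
#'   accuracy, and the two `null_eval` objects.
#' @export
evaluate_predictions <- function(predicted, observed_repression,
                                 n_perm = 1000L, n_boot = 1000L, seed = 1L) {
  if (is.factor(predicted)) predicted <- as.integer(predicted)
  fit <- optimize_thresholds(observed_repression, predicted)
  observed_class <- bin_observed(observed_repression, fit$thresholds)
  core <- confusion_and_accuracy(predicted, observed_class)
  seeds <- fanout_seeds(seed, 2L)
  structure(
    list(
      thresholds = fit$thresholds,
      confusion = core$confusion,
      accuracy = core$accuracy,
      observed_class = observed_class,
      predicted_class = predicted,
      permutation = permutation_null(predicted, observed_class,
                                     n_perm = n_perm, seed = seeds[1]),
      bootstrap = bootstrap_random_null(predicted, observed_class,
                                        n_runs = n_boot, seed = seeds[2]),
      seed = as.integer(seed)
    ),
    class = "synear_eval"
  )
}

#' @export
print.synear_eval <- function(x, ...) {
  cat("SynEAR prediction evaluation (n =", length(x$predicted_class), ")\n")
  cat(sprintf("  accuracy: %.1f%%  (thresholds: %s)\n", 100 * x$accuracy,
              paste(signif(x$thresholds, 4), collapse = ", ")))
  cat(sprintf("  permutation null: mean %.1f%%, sd %.2f%%, outperformed %.1f%%, p = %.4g\n",
              100 * x$permutation$null_mean, 100 * x$permutation$null_sd,
              x$permutation$percentile_outperformed,
              x$permutation$p_two_tailed_empirical))
  cat(sprintf("  random-guess null: mean %.1f%%, sd %.2f%%, outperformed %.1f%%, p = %.4g\n",
              100 * x$bootstrap$null_mean, 100 * x$bootstrap$null_sd,
              x$bootstrap$percentile_outperformed,
              x$bootstrap$p_two_tailed_empirical))
  invisible(x)
}
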