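test_that("binning uses half-open intervals with the value at a threshold
          going up", {
  th <- c(0.25, 0.5, 0.75)
  expect_equal(bin_observed(0.1, th), 1L)
  expect_equal(bin_observed(0.5, th), 3L)
  expect_equal(bin_observed(c(0.0, 0.2), th), c(1L, 1L))
  expect_equal(bin_observed(c(0.3, 0.8, 2), th), c(2L, 4L, 4L))
  expect_error(bin_observed(0.5, c(0.5, 0.5, 0.7)), "strictly increasing")
})

test_that("threshold optimization separates separable data perfectly", {
  fit <- optimize_thresholds(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 4, 4))
  expect_equal(fit$accuracy, 1)
  expect_equal(bin_observed(c(0.1, 0.2, 0.8, 0.9), fit$thresholds),
               c(1L, 1L, 4L, 4L))

  # constant predictions are satisfiable with degenerate outer thresholds
  fit1 <- optimize_thresholds(c(0.1, 0.4, 0.6, 0.9), rep(1L, 4))
  expect_equal(fit1$accuracy, 1)
  expect_equal(bin_observed(c(0.1, 0.4, 0.6, 0.9), fit1$thresholds),
               rep(1L, 4))
  expect_error(optimize_thresholds(c(1, 1, 1, 2), c(1, 2, 3, 4)),
               "distinct")
})

test_that("threshold optimization equals exhaustive midpoint search", {
  set.seed(17)
  for (i in 1:25) {
    n <- sample(6:12, 1)
    values <- round(runif(n), 2)
    if (length(unique(values)) < 4) next
    predicted <- sample(1:4, n, replace = TRUE)
    fit <- optimize_thresholds(values, predicted)
    expect_equal(fit$accuracy, thresholds_brute(values, predicted))
    # the returned thresholds actually achieve the reported accuracy
    expect_equal(mean(bin_observed(values, fit$thresholds) == predicted),
                 fit$accuracy)
  }
})

test_that("accuracy depends on observed values only through their ranks", {
  set.seed(23)
  values <- runif(20)
  predicted <- sample(1:4, 20, replace = TRUE)
  a1 <- optimize_thresholds(values, predicted)$accuracy
  a2 <- optimize_thresholds(exp(3 * values) - 1, predicted)$accuracy
  expect_equal(a1, a2)
})

test_that("confusion matrix counts and accuracy match manual tallies", {
  perfect <- confusion_and_accuracy(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$confusion, diag(1L, 4),
               ignore_attr = TRUE)

  reversed <- confusion_and_accuracy(rep(1:4, each = 2), rep(4:1, each = 2))
  expect_equal(sum(diag(reversed$confusion)), 0)

  pred <- c(1, 1, 2, 2, 3, 4, 4, 4)
  obs <- c(1, 2, 2, 2, 3, 3, 4, 4)
  got <- confusion_and_accuracy(pred, obs)
  expect_equal(got$accuracy, 6 / 8)
  expect_equal(got$confusion[1, 1], 1L)
  expect_equal(got$confusion[1, 2], 1L)
  expect_equal(got$confusion[2, 2], 2L)
  expect_equal(got$confusion[4, 3], 1L)
  expect_equal(got$confusion[4, 4], 2L)
  expect_equal(sum(got$confusion), 8)
  expect_error(confusion_and_accuracy(1:3, 1:4), "equal length")
})

test_that("permutation null matches its closed-form expectation", {
  set.seed(31)
  predicted <- sample(1:4, 80, replace = TRUE, prob = c(0.4, 0.3, 0.2, 0.1))
  observed <- sample(1:4, 80, replace = TRUE)
  null <- permutation_null(predicted, observed, n_perm = 1000, seed = 7)
  n <- 80
  expected <- sum(tabulate(predicted, 4) * tabulate(observed, 4)) / n^2
  se <- null$null_sd / sqrt(null$n_iterations)
  expect_lt(abs(null$null_mean - expected), 3 * se)
  # deterministic under a fixed seed
  null2 <- permutation_null(predicted, observed, n_perm = 1000, seed = 7)
  expect_identical(null$null_accuracies, null2$null_accuracies)
  # degenerate exchangeable case: constant predictions make every
  # permutation score exactly the class share
  const <- permutation_null(rep(1L, 20), rep(1:4, 5), n_perm = 100, seed = 1)
  expect_equal(unique(const$null_accuracies), 0.25)
  expect_equal(const$real_accuracy, 0.25)
})

test_that("random-guess bootstrap has mean 1/4 and binomial spread", {
  obs <- rep(1:4, each = 20)
  pred <- rep(1L, 80)
  null <- bootstrap_random_null(pred, obs, n_runs = 1000, seed = 5)
  n <- 80
  sd_theory <- sqrt(0.25 * 0.75 / n)
  expect_lt(abs(null$null_mean - 0.25), 3 * sd_theory / sqrt(1000))
  se_sd <- sd_theory / sqrt(2 * (1000 - 1))
  expect_lt(abs(null$null_sd - sd_theory), 3 * se_sd)
  # single observation: accuracy per run is Bernoulli
  tiny <- bootstrap_random_null(1L, 2L, n_runs = 200, seed = 9)
  expect_true(all(tiny$null_accuracies %in% c(0, 1)))
})

test_that("two-tailed p-values use the +1-corrected doubled tail", {
  obs <- rep(1:4, each = 10)
  pred <- obs  # perfect predictions
  null <- permutation_null(pred, obs, n_perm = 199, seed = 3)
  k_ge <- sum(null$null_accuracies >= 1)
  expect_equal(null$p_two_tailed_empirical,
               min(1, 2 * (k_ge + 1) / 200))
  expect_equal(null$percentile_outperformed,
               100 * mean(null$null_accuracies < 1))
  expect_lt(null$p_two_tailed_normal, 1e-6)
})

test_that("full evaluation is reproducible and holds thresholds fixed", {
  set.seed(53)
  observed <- runif(40)
  predicted <- pmin(4L, pmax(1L, as.integer(ceiling(observed * 4) +
                                              sample(-1:1, 40, TRUE))))
  ev1 <- evaluate_predictions(predicted, observed, n_perm = 200,
                              n_boot = 200, seed = 11)
  ev2 <- evaluate_predictions(predicted, observed, n_perm = 200,
                              n_boot = 200, seed = 11)
  expect_identical(ev1, ev2)
  expect_equal(sum(ev1$confusion), 40)
  expect_equal(ev1$accuracy, sum(diag(ev1$confusion)) / 40)
  expect_true(all(diff(ev1$thresholds) > 0))
})
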