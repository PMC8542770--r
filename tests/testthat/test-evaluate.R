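# Evaluation: error summaries, age groups, random-selection tests, and the
# nonparametric comparisons.

test_that("MAE/SD summary follows its conventions", {
  expect_equal(mae_sd(c(0.1, -0.1, 0.2, -0.2))[["mae"]], 0.15)
  expect_equal(unname(mae_sd(rep(0, 5))), c(0, 0))
  expect_equal(mae_sd(0.7)[["sd"]], 0)      # single subject
})

test_that("the nine age groups tile the cohort range with half-open edges", {
  expect_identical(age_group_label(22.9), 1L)
  expect_identical(age_group_label(16), 1L)
  expect_identical(age_group_label(23), 2L)
  expect_identical(age_group_label(24.99), 2L)
  expect_identical(age_group_label(25), 3L)
  expect_identical(age_group_label(38.7), 9L)  # cohort maximum maps
  expect_error(age_group_label(15.5), "outside")
  expect_error(age_group_label(39), "outside")
})

test_that("random-selection p-values are exact strict proportions", {
  # perfect predictions: null distributions degenerate at zero; the strict
  # '<' convention gives p = 0 against a zero reference
  preds <- simulate_prediction_cohort(n_subjects = 20, n_pred = 8,
                                      noise_sd = 0, contam_rate = 0, seed = 5)
  rst <- random_selection_test(preds, reference_mae = 0, reference_sd = 0,
                               "single_slice", n_rep = 500, seed = 1)
  expect_true(all(rst$null_mae == 0))
  expect_identical(rst$p_mae, 0)
  # against any positive reference every degenerate replicate wins
  rst2 <- random_selection_test(preds, 0.1, 0.1, "single_slice",
                                n_rep = 500, seed = 1)
  expect_identical(rst2$p_mae, 1)
  # p * n_rep is an integer by construction
  noisy <- simulate_prediction_cohort(n_subjects = 30, seed = 8)
  agg <- aggregate_cohort(noisy, "mode", 0.2)
  ref <- mae_sd(agg$pad)
  r3 <- random_selection_test(noisy, ref[["mae"]], ref[["sd"]],
                              "single_stack", n_rep = 777, seed = 2)
  expect_equal(r3$p_mae * 777, round(r3$p_mae * 777))
  expect_equal(r3$p_sd * 777, round(r3$p_sd * 777))
  # reproducible bit-for-bit
  r4 <- random_selection_test(noisy, ref[["mae"]], ref[["sd"]],
                              "single_stack", n_rep = 777, seed = 2)
  expect_identical(r3$null_mae, r4$null_mae)
})

test_that("one slice per subject collapses the null distribution", {
  preds <- simulate_prediction_cohort(n_subjects = 10, n_pred = 1, seed = 3)
  rst <- random_selection_test(preds, 0.5, 0.5, "single_slice",
                               n_rep = 50, seed = 9)
  expect_equal(length(unique(rst$null_mae)), 1L)
})

test_that("measure comparison detects a uniformly worse measure", {
  set.seed(21)
  base <- abs(rnorm(50, 0, 0.3))
  mats <- cbind(mean = base + 1, median = base, mode = base)
  cmp <- compare_measures(mats)
  expect_lt(cmp$friedman$p, 0.001)
  pw <- cmp$pairwise
  expect_lt(pw$p[pw$measure_a == "mean" & pw$measure_b == "median"], 0.01)
  # identical columns: no effect
  same <- cbind(a = base, b = base, c = base)
  expect_gt(compare_measures(same)$friedman$p, 0.9)
  expect_error(compare_measures(cbind(a = c(base, NA), b = c(base, 1))),
               "unpaired")
})

test_that("Kruskal-Wallis over age groups is calibrated under the null", {
  set.seed(31)
  rej <- mean(replicate(400, {
    ga <- runif(90, 16, 38.5)
    pads <- abs(rnorm(90, 0, 0.3))
    compare_age_groups(pads, ga)$p < 0.05
  }))
  expect_equal(rej, 0.05, tolerance = 0.5)  # 5% +/- 2.5 points
})

test_that("architecture comparison flags a degraded arm on paired stacks", {
  set.seed(41)
  base <- abs(rnorm(100, 0, 0.3))
  mats <- cbind(single_channel = base,
                volumetric = abs(base + rnorm(100, 0.5, 0.2)))
  cmp <- compare_architectures(mats)
  expect_identical(nrow(cmp), 1L)
  expect_lt(cmp$p, 0.001)
  expect_true(all(c("n", "statistic", "p") %in% names(cmp)))
  expect_error(compare_architectures(cbind(a = c(1, NA), b = c(1, 2))),
               "mismatched")
})
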