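test_that("classification threshold uses the >= convention", {
  expect_true(classify(0.5, 0.5))
  expect_false(classify(0.49, 0.5))
  expect_equal(classify(c(0, 0.2, 1), threshold = 0), rep(TRUE, 3))
  expect_error(classify(1.2), "\\[0, 1\\]")
})

test_that("confusion metrics count and normalize correctly", {
  perfect <- confusion_metrics(c(TRUE, FALSE, TRUE), c(TRUE, FALSE, TRUE))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$tpr, 1)
  expect_equal(perfect$tnr, 1)

  # all-detect predictions against 3 detects / 2 nondetects
  all_det <- confusion_metrics(rep(TRUE, 5),
                               c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(all_det$accuracy, 0.6)
  expect_equal(all_det$tpr, 1)
  expect_equal(all_det$tnr, 0)
  expect_equal(all_det$tp + all_det$fp + all_det$tn + all_det$fn, 5)

  # empty observed class: the rate is reported as absent
  no_neg <- confusion_metrics(c(TRUE, FALSE), c(TRUE, TRUE))
  expect_true(is.na(no_neg$tnr))
  expect_error(confusion_metrics(TRUE, c(TRUE, FALSE)), "equal length")
})

test_that("AUC is the Mann-Whitney pair statistic with 0.5 tie credit", {
  # {0.9:+, 0.8:-, 0.7:+, 0.6:-}: 3 of 4 pos-neg pairs correctly ordered
  expect_equal(auc(c(0.9, 0.8, 0.7, 0.6), c(TRUE, FALSE, TRUE, FALSE)), 0.75)
  expect_equal(auc(rep(0.4, 6), c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE)),
               0.5)
  expect_equal(auc(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_error(auc(c(0.1, 0.9), c(TRUE, TRUE)), "both classes")
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(10)
  for (rep in 1:5) {
    scores <- round(runif(200), 2)  # rounding forces ties
    flags <- runif(200) < plogis(3 * (scores - 0.5))
    if (!any(flags) || all(flags)) next
    reference <- suppressMessages(
      as.numeric(pROC::auc(pROC::roc(flags, scores, quiet = TRUE)))
    )
    expect_equal(auc(scores, flags), reference, tolerance = 1e-12)
  }
})

test_that("concentration error metrics follow their definitions", {
  expect_equal(rmse_true_positives(c(1, 2, 3), c(1, 2, 3), rep(TRUE, 3)), 0)
  expect_equal(rmse_true_positives(c(2, 3, 4), c(1, 2, 3), rep(TRUE, 3)), 1)
  expect_equal(rmse_true_positives(c(1, 2, 0), c(0, 0, 0), rep(TRUE, 3)),
               sqrt(5 / 3))
  # the mask restricts the computation
  expect_equal(rmse_true_positives(c(9, 2), c(0, 2), c(FALSE, TRUE)), 0)
  expect_error(rmse_true_positives(1, 1, FALSE), "no cases")

  expect_equal(frac_within_k_orders(c(1, 2), c(1, 2)), 1)
  expect_equal(frac_within_k_orders(c(0.5, 1.5), c(0, 0)), 0.5)
  # boundary: an error of exactly k counts as within
  expect_equal(frac_within_k_orders(1, 0, k = 1), 1)
})

test_that("combined hurdle accuracy requires flag and magnitude agreement", {
  # all nondetect, all predicted nondetect
  expect_equal(combined_hurdle_accuracy(rep(FALSE, 3), rep(0, 3),
                                        rep(FALSE, 3), rep(NA_real_, 3)), 1)
  # observed detect, predicted detect, error 1.2: failure
  expect_equal(combined_hurdle_accuracy(TRUE, 1.2, TRUE, 0), 0)
  # mixed four-case example: success, success, flag miss, magnitude miss
  got <- combined_hurdle_accuracy(
    pred_flags = c(FALSE, TRUE, TRUE, TRUE),
    pred_conc = c(0, 1.0, 0, 5),
    obs_flags = c(FALSE, TRUE, FALSE, TRUE),
    obs_conc = c(NA, 0.5, NA, 0)
  )
  expect_equal(got, 0.5)
})

test_that("the null baseline uses training rate and mean alone", {
  train <- obs_table(sprintf("I%d", 1:10), "S1", "1101", "11",
                     detected = rep(c(TRUE, FALSE), c(6, 4)),
                     log10_conc = c(1, 2, 3, 1, 2, 3, rep(NA, 4)))
  null <- null_model(train)
  expect_equal(null$p_detect, 0.6)
  expect_equal(null$conc_mean, 2)
  # constant scores give AUC 0.5 exactly
  expect_equal(auc(rep(null$p_detect, 10), train$detected), 0.5)
  # null RMSE is zero on cases equal to the training mean
  expect_equal(rmse_true_positives(rep(null$conc_mean, 3), rep(2, 3),
                                   rep(TRUE, 3)), 0)
  # no detects: concentration part absent
  nd <- train; nd$detected <- FALSE; nd$log10_conc <- NA_real_
  expect_true(is.na(null_model(nd)$conc_mean))
  expect_error(null_model(train[0, ]), "empty")

  # deterministic vs base-rate-sampling classification variants
  expect_equal(null_flags(null, 4, "threshold"), rep(TRUE, 4))
  set_flags <- null_flags(null, 10000, "sample", seed = 1)
  expect_equal(mean(set_flags), 0.6, tolerance = 0.03)
  expect_identical(null_flags(null, 100, "sample", seed = 2),
                   null_flags(null, 100, "sample", seed = 2))
})

test_that("metrics are invariant to row permutation", {
  set.seed(11)
  n <- 60
  p <- runif(n)
  flags <- runif(n) < p
  if (!any(flags)) flags[1] <- TRUE
  if (all(flags)) flags[2] <- FALSE
  conc <- rnorm(n)
  obs_conc <- conc + rnorm(n)
  perm <- sample(n)
  expect_equal(auc(p, flags), auc(p[perm], flags[perm]))
  cm1 <- confusion_metrics(p >= 0.5, flags)
  cm2 <- confusion_metrics((p >= 0.5)[perm], flags[perm])
  expect_equal(cm1, cm2)
  expect_equal(frac_within_k_orders(conc, obs_conc),
               frac_within_k_orders(conc[perm], obs_conc[perm]))
})

test_that("the evaluation report compares model and null on equal terms", {
  fx <- study_fixture()
  ev <- fx$evaluation
  expect_setequal(ev$metric,
                  c("tp", "fp", "tn", "fn", "accuracy", "tpr", "tnr", "auc",
                    "rmse_tp", "frac_within_k", "combined_accuracy"))
  counts <- ev$model[ev$metric %in% c("tp", "fp", "tn", "fn")]
  expect_equal(sum(counts), nrow(fx$test))
  expect_equal(ev$null[ev$metric == "auc"], 0.5)
  rates <- ev$model[ev$metric %in% c("accuracy", "tpr", "tnr",
                                     "frac_within_k", "combined_accuracy")]
  expect_true(all(rates >= 0 & rates <= 1))
})
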