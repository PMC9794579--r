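test_that("roc_auc_ovr matches exhaustive pairwise counting", {
  expect_equal(roc_auc_ovr(c("+", "+", "-", "-"), c(0.9, 0.4, 0.6, 0.2), "+"),
               0.75)
  expect_equal(roc_auc_ovr(c("+", "+", "-", "-"), c(0.9, 0.8, 0.2, 0.1), "+"), 1)
  expect_equal(roc_auc_ovr(c("+", "+", "-", "-"), rep(0.5, 4), "+"), 0.5)
  expect_true(is.na(roc_auc_ovr(c("+", "+"), c(0.1, 0.2), "+")))
})

test_that("roc_auc_ovr agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(21, {
    for (i in 1:10) {
      lab <- sample(c("pos", "neg"), 30, replace = TRUE, prob = c(0.4, 0.6))
      if (length(unique(lab)) < 2) next
      sc <- round(runif(30), 2)  # rounding forces ties
      ours <- roc_auc_ovr(lab, sc, "pos")
      ref <- suppressMessages(as.numeric(pROC::auc(
        pROC::roc(lab, sc, levels = c("neg", "pos"), direction = "<"))))
      expect_equal(ours, ref)
    }
  })
})

test_that("confusion_metrics reproduces a hand-computed 3-class confusion", {
  # confusion rows (true high/intermediate/low): (4,0,0) / (1,5,1) / (0,2,3)
  labels <- c(rep("high", 4), rep("intermediate", 7), rep("low", 5))
  preds <- c(rep("high", 4),
             "high", rep("intermediate", 5), "low",
             rep("intermediate", 2), rep("low", 3))
  cm <- confusion_metrics(labels, preds)
  per <- cm$per_class
  expect_equal(per$lr_pos[per$class == "high"], 1 / (1 / 12))          # 12
  expect_equal(per$lr_neg[per$class == "high"], 0)
  expect_equal(per$lr_pos[per$class == "intermediate"], (5 / 7) / (2 / 9))
  expect_equal(per$lr_neg[per$class == "intermediate"], (2 / 7) / (7 / 9))
  expect_equal(per$lr_pos[per$class == "low"], (3 / 5) / (1 / 11))
  expect_equal(per$lr_neg[per$class == "low"], (2 / 5) / (10 / 11))
  expect_equal(cm$accuracy, 12 / 16)
  expect_equal(cm$f1, mean(c(8 / 9, 5 / 7, 2 / 3)))

  expect_error(confusion_metrics(character(0), character(0)), "non-empty")
  expect_error(confusion_metrics(labels, preds[-1]), "length")
})

test_that("perfect predictions give degenerate likelihood ratios", {
  labels <- rep(TDP_RISKS, times = c(4, 7, 5))
  cm <- confusion_metrics(labels, labels)
  expect_equal(cm$accuracy, 1)
  expect_true(all(cm$per_class$lr_neg == 0))
  expect_true(all(is.infinite(cm$per_class$lr_pos)))
})

test_that("run_repeated_test resamples one series per drug and aggregates", {
  drugs <- dplyr::filter(fixture_drugs(), split == "test")
  pool <- gen_variability_pool(drugs, per_drug = 6, length = 40, seed = 61)
  fit <- train_cnn(
    assemble_training_set(pool, drugs, per_drug = 4, seed = 62),
    tiny_cnn_config(epochs = 2, folds = 2, seed = 63)
  )
  res <- run_repeated_test(fit, pool, n_iter = 25, seed = 64)
  expect_equal(res$n_iterations, 25)
  expect_equal(nrow(res$iterations), 25)
  s <- res$summary
  expect_true(all(s$median >= s$min & s$median <= s$max, na.rm = TRUE))
  auc <- s[s$metric == "auc", ]
  expect_true(all(auc$median >= 0 & auc$median <= 1))

  res2 <- run_repeated_test(fit, pool, n_iter = 25, seed = 64)
  expect_identical(res$summary, res2$summary)

  expect_error(run_repeated_test(fit, pool, n_iter = 0), "n_iter")
})

test_that("a single-series-per-drug pool collapses min = median = max", {
  drugs <- dplyr::filter(fixture_drugs(), split == "test")
  pool <- gen_variability_pool(drugs, per_drug = 1, length = 40, seed = 71)
  fit <- train_cnn(
    assemble_training_set(
      gen_variability_pool(drugs, per_drug = 4, length = 40, seed = 72),
      drugs, per_drug = 3, seed = 73),
    tiny_cnn_config(epochs = 2, folds = 2, seed = 74)
  )
  res <- run_repeated_test(fit, pool, n_iter = 50, seed = 75)
  ok <- is.finite(res$summary$median)
  expect_equal(res$summary$min[ok], res$summary$median[ok])
  expect_equal(res$summary$max[ok], res$summary$median[ok])

  # n_iter = 1 equals a direct single evaluation
  one <- run_repeated_test(fit, pool, n_iter = 1, seed = 76)
  p <- predict(fit, pool$values, type = "class")
  direct <- confusion_metrics(pool$meta$risk, as.character(p))
  expect_equal(one$iterations$accuracy, direct$accuracy)
})

test_that("a sharply separated pool yields perfect median metrics", {
  drugs <- dplyr::filter(fixture_drugs(), split == "test")
  spec <- synthetic_class_spec(mean = c(high = 0, intermediate = 5, low = 10),
                               sd = c(0.01, 0.01, 0.01),
                               alternans = c(0, 0, 0), drug_offset_sd = 0.01)
  pool <- gen_variability_pool(drugs, spec, per_drug = 6, length = 40, seed = 81)
  fit <- train_cnn(assemble_training_set(pool, drugs, per_drug = 4, seed = 82),
                   tiny_cnn_config(epochs = 2000, folds = 3, seed = 83))
  res <- run_repeated_test(fit, pool, n_iter = 40, seed = 84)
  g <- glance(res)
  expect_equal(g$auc_high, 1)
  expect_equal(g$auc_intermediate, 1)
  expect_equal(g$auc_low, 1)
  expect_equal(g$accuracy, 1)
})
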