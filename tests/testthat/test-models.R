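test_that("binary datasets restrict and relabel correctly", {
  scores <- fixture_score_table()
  d <- make_binary_dataset(scores, "C_vs_B")
  expect_equal(sort(unique(d$group)), c("B", "C"))
  expect_equal(nrow(d), (18 + 14) * 5)
  expect_equal(sum(d$.label == "pos"), 14 * 5)  # positive = B

  d2 <- make_binary_dataset(scores, "C_vs_ALS")
  expect_equal(nrow(d2), 63 * 5)
  expect_equal(sum(d2$.label == "pos"), 45 * 5)  # every ALS row positive

  d3 <- make_binary_dataset(scores, "B_vs_NB")
  expect_false(any(d3$group == "C"))
  expect_error(make_binary_dataset(scores[scores$group == "C", ], "C_vs_B"),
               "zero rows")
  expect_error(make_binary_dataset(scores, "X_vs_Y"), "unknown comparison")
})

test_that("upsampling balances classes with replacement, deterministically", {
  d <- tibble::tibble(
    .label = factor(rep(c("neg", "pos"), c(10, 5)), levels = c("neg", "pos")),
    PC1 = rnorm(15)
  )
  up <- upsample_training(d, seed = 3)
  expect_equal(unname(table(up$.label)), c(10L, 10L), ignore_attr = TRUE)
  # original rows all still present
  expect_true(all(d$PC1 %in% up$PC1))
  expect_identical(upsample_training(d, seed = 3), up)
  # already balanced: unchanged
  bal <- d[c(1:5, 11:15), ]
  expect_identical(upsample_training(bal, seed = 3), bal)
  single <- d[d$.label == "neg", ]
  expect_error(upsample_training(single), "single class")
})

test_that("thresholding uses p >= threshold as positive", {
  p <- c(0.95, 0.60, 0.50, 0.949999)
  expect_equal(as.character(apply_threshold(p, 0.95)),
               c("pos", "neg", "neg", "neg"))
  expect_equal(as.character(apply_threshold(p, 0.5)),
               c("pos", "pos", "pos", "pos"))
  expect_error(apply_threshold(c(0.5, 1.2), 0.5), "\\[0, 1\\]")
})

test_that("confusion metrics implement the three ratios", {
  m <- confusion_metrics(list(tp = 9, fn = 1, tn = 8, fp = 2))
  expect_equal(unlist(m), c(accuracy = 85, sensitivity = 90,
                            specificity = 80))
  all_right <- confusion_metrics(list(tp = 5, fn = 0, tn = 5, fp = 0))
  expect_equal(unlist(all_right), c(accuracy = 100, sensitivity = 100,
                                    specificity = 100))
  no_pos <- confusion_metrics(list(tp = 0, fn = 0, tn = 5, fp = 0))
  expect_true(is.na(no_pos$sensitivity))
  expect_equal(no_pos$specificity, 100)
  expect_error(confusion_metrics(list(tp = 0, fn = 0, tn = 0, fp = 0)),
               "empty")
})

test_that("every model separates well-separated blobs perfectly in training", {
  d <- withr::with_seed(8, {
    n <- 40
    tibble::tibble(
      .label = factor(rep(c("neg", "pos"), each = n),
                      levels = c("neg", "pos")),
      PC1 = c(rnorm(n, -3), rnorm(n, 3)),
      PC2 = rnorm(2 * n),
      PC3 = rnorm(2 * n)
    )
  })
  for (m in phonatory_models()) {
    fit <- fit_model(m, d, seed = 1)
    p <- predict(fit, d)
    expect_true(all(p >= 0 & p <= 1))
    acc <- mean((p >= 0.5) == (d$.label == "pos"))
    expect_equal(acc, 1, label = paste(m, "training accuracy"))
  }
})

test_that("label-shuffled data yield chance-level cross-validated accuracy", {
  d <- withr::with_seed(21, {
    tibble::tibble(
      .label = factor(sample(rep(c("neg", "pos"), 60)),
                      levels = c("neg", "pos")),
      PC1 = rnorm(120), PC2 = rnorm(120)
    )
  })
  res <- repeated_kfold_evaluate(d, "lda", cv_scheme(trials = 3, seed = 4),
                                 thresholds = 0.5)
  acc <- mean(res$accuracy)
  expect_lt(abs(acc - 50), 15)  # 3 SE of binomial noise at this size
})

test_that("SVM tuning selects a cost from the fixed grid", {
  d <- withr::with_seed(9, {
    tibble::tibble(
      .label = factor(rep(c("neg", "pos"), each = 30),
                      levels = c("neg", "pos")),
      PC1 = c(rnorm(30, -3), rnorm(30, 3)), PC2 = rnorm(60)
    )
  })
  fit <- fit_model("svm", d, seed = 2)
  expect_true(fit$tuned$cost %in% c(0.0001, 0.0005, 0.001, 0.01, 0.1, 1))
  rf <- fit_model("rf", d, seed = 2)
  expect_true(rf$tuned$mtry %in% c(1, 2))
  expect_equal(rf$fit$ntree, 500)
})

test_that("single-class training folds are an error", {
  d <- tibble::tibble(.label = factor(rep("pos", 10),
                                      levels = c("neg", "pos")),
                      PC1 = rnorm(10))
  expect_error(fit_model("lda", d), "single class")
})
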