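test_that("cv_scheme validates and partitions have full coverage", {
  expect_error(cv_scheme(k = 1), "at least 2")
  expect_error(cv_scheme(trials = 0), "at least 1")
  d <- fixture_score_table(n_c = 6, n_b = 5, n_nb = 0)
  d <- make_binary_dataset(d, "C_vs_B")
  scheme <- cv_scheme(k = 10, trials = 4, seed = 7)
  parts <- phonatory:::make_partitions(d, scheme)
  expect_length(parts, 4)
  for (p in parts) {
    # every row in exactly one test chunk; chunk sizes near-equal
    expect_length(p, nrow(d))
    expect_equal(sort(unique(p)), 1:10)
    expect_lte(diff(range(table(p))), 1)
  }
  # partitions differ across trials (fresh permutation each trial)
  expect_false(identical(parts[[1]], parts[[2]]))
})

test_that("subject-grouped partitions never split a subject", {
  d <- make_binary_dataset(fixture_score_table(), "C_vs_B")
  scheme <- cv_scheme(k = 5, trials = 2, seed = 3, group_by_subject = TRUE)
  parts <- phonatory:::make_partitions(d, scheme)
  for (p in parts) {
    per_subject <- tapply(p, d$subject_id, function(v) length(unique(v)))
    expect_true(all(per_subject == 1))
  }
})

test_that("repeated k-fold produces the full fold grid deterministically", {
  d <- make_binary_dataset(fixture_score_table(n_c = 8, n_b = 8, n_nb = 0),
                           "C_vs_B")
  scheme <- cv_scheme(k = 10, trials = 10, seed = 5)
  res <- repeated_kfold_evaluate(d, "lda", scheme, thresholds = c(0.5, 0.95))
  expect_equal(nrow(res), 10 * 10 * 2)  # trials x folds x thresholds
  expect_equal(sum(res$threshold == 0.5), 100)
  res2 <- repeated_kfold_evaluate(d, "lda", scheme,
                                  thresholds = c(0.5, 0.95))
  expect_identical(as.data.frame(res), as.data.frame(res2))
})

test_that("per-fold metrics satisfy the confusion identities", {
  d <- make_binary_dataset(fixture_score_table(n_c = 8, n_b = 8, n_nb = 0),
                           "C_vs_B")
  res <- repeated_kfold_evaluate(d, "lr", cv_scheme(trials = 2, seed = 6))
  total <- res$tp + res$fn + res$tn + res$fp
  # every test row accounted for, within-trial totals = n
  expect_true(all(tapply(total[res$threshold == 0.5],
                         res$trial[res$threshold == 0.5], sum) == nrow(d)))
  # accuracy is the prevalence-weighted combination of sens and spec
  ok <- !is.na(res$sensitivity) & !is.na(res$specificity)
  lhs <- res$accuracy[ok]
  rhs <- (res$sensitivity[ok] * (res$tp + res$fn)[ok] +
            res$specificity[ok] * (res$tn + res$fp)[ok]) / total[ok]
  expect_equal(lhs, rhs, tolerance = 1e-10)
  expect_true(all(res$accuracy >= 0 & res$accuracy <= 100))
})

test_that("threshold 0.95 never raises sensitivity nor lowers specificity", {
  d <- make_binary_dataset(fixture_score_table(sep = 1.5), "C_vs_B")
  res <- repeated_kfold_evaluate(d, "lr", cv_scheme(trials = 2, seed = 8))
  wide <- tidyr::pivot_wider(
    dplyr::select(tibble::as_tibble(res), dplyr::all_of(
      c("threshold", "trial", "fold", "sensitivity", "specificity"))),
    names_from = "threshold",
    values_from = c("sensitivity", "specificity"))
  expect_true(all(wide$`sensitivity_0.95` <= wide$`sensitivity_0.5` + 1e-9,
                  na.rm = TRUE))
  expect_true(all(wide$`specificity_0.95` >= wide$`specificity_0.5` - 1e-9,
                  na.rm = TRUE))
})

test_that("model comparisons pair folds and Bonferroni-correct", {
  d <- make_binary_dataset(fixture_score_table(sep = 2.5), "C_vs_B")
  scheme <- cv_scheme(trials = 2, seed = 9)
  parts <- phonatory:::make_partitions(d, scheme)
  res <- dplyr::bind_rows(
    repeated_kfold_evaluate(d, "lda", scheme, 0.5, parts),
    repeated_kfold_evaluate(d, "lr", scheme, 0.5, parts),
    repeated_kfold_evaluate(d, "nab", scheme, 0.5, parts)
  )
  cm <- compare_models(res, threshold = 0.5)
  expect_equal(nrow(cm), 3)  # 3 pairs of 3 models
  expect_true(all(cm$p_adjusted >= cm$p_value - 1e-15))
  expect_true(all(cm$p_adjusted <= 1))

  # a model against an identical copy of itself: degenerate, p = 1
  twin <- res[res$model == "lda", ]
  twin$model <- "twin"
  cm2 <- compare_models(dplyr::bind_rows(res[res$model == "lda", ], twin),
                        threshold = 0.5)
  expect_true(cm2$degenerate)
  expect_equal(cm2$p_value, 1)
  expect_false(cm2$significant)
})

test_that("results_report demands the full grid and formats to one decimal", {
  d <- fixture_score_table(n_c = 8, n_b = 8, n_nb = 8)
  res <- evaluate_models(d, comparisons = c("C_vs_B", "B_vs_NB"),
                         models = c("lda", "lr"),
                         scheme = cv_scheme(trials = 1, seed = 2))
  tabs <- results_report(res, models = c("lda", "lr"),
                         comparisons = c("C_vs_B", "B_vs_NB"))
  expect_named(tabs, c("threshold_50pct", "threshold_95pct"))
  t50 <- tabs$threshold_50pct
  expect_equal(nrow(t50), 2 * 3)  # 2 models x 3 metrics
  expect_true(all(c("C_vs_B", "B_vs_NB") %in% names(t50)))
  expect_equal(t50$C_vs_B, round(t50$C_vs_B, 1))
  expect_error(
    results_report(res, models = c("lda", "lr", "svm"),
                   comparisons = c("C_vs_B", "B_vs_NB")),
    "missing grid cells")
})
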