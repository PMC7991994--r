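test_that("build_feature_table joins, warns and errors as specified", {
  tab <- fixture_feature_table()
  meta <- dplyr::distinct(tab[, c("subject_id", "sex", "age_years", "group")])
  feats <- tab
  built <- build_feature_table(feats, meta)
  expect_equal(nrow(built), nrow(tab))

  orphan <- feats
  orphan$subject_id[1] <- "GHOST"
  expect_error(build_feature_table(orphan, meta), "GHOST")

  dup <- dplyr::bind_rows(feats, feats[1, ])
  expect_error(build_feature_table(dup, meta), "duplicated")

  # 5-vowel table with one utterance missing -> fewer rows plus a warning
  five <- tidyr::crossing(feats[1:3, "subject_id"],
                          vowel = c("a", "e", "i", "o", "u")) |>
    dplyr::left_join(feats[, c("subject_id",
                               phonatory_feature_names)],
                     by = "subject_id")
  five <- five[-2, ]
  expect_warning(build_feature_table(five, meta), "missing vowels")
})

test_that("apq11 imputation follows the same-subject other-vowel mean", {
  tab <- tidyr::crossing(subject_id = c("P1", "P2"),
                         vowel = c("a", "e", "i", "o", "u"))
  tab$shimmer_apq11_pct <- c(2, 4, NA, 4, 2, 1, 1, 1, 1, 1)
  out <- impute_apq11(tab)
  expect_equal(out$shimmer_apq11_pct[3], 3)
  expect_equal(attr(out, "n_imputed"), 1)
  # idempotent on complete tables
  again <- impute_apq11(out)
  expect_equal(again$shimmer_apq11_pct, out$shimmer_apq11_pct)
  # a subject with no defined value has no rule
  allna <- tab
  allna$shimmer_apq11_pct[allna$subject_id == "P1"] <- NA
  expect_error(impute_apq11(allna), "every vowel")
})

test_that("age slopes are recovered exactly from noiseless linear controls", {
  tab <- fixture_feature_table()
  # overwrite one feature with an exact line: 2 * age + 5
  tab$jitter_relative_pct <- 2 * tab$age_years + 5
  m <- fit_age_correction(tab)
  sl <- m$slopes
  expect_equal(sl$slope[sl$feature == "jitter_relative_pct"], 2,
               tolerance = 1e-10)
  # age-independent feature: slope ~ 0
  tab$hnr_sd_db <- 1.25
  m2 <- fit_age_correction(tab)
  expect_equal(m2$slopes$slope[m2$slopes$feature == "hnr_sd_db"], 0,
               tolerance = 1e-10)
  # degenerate ages
  bad <- tab
  bad$age_years[bad$group == "C"] <- 50
  expect_error(fit_age_correction(bad), "degenerate")
})

test_that("removing age effects recovers pure group offsets", {
  tab <- fixture_feature_table()
  offset <- ifelse(tab$group == "B", 3, 0)
  tab$shimmer_db <- 2 * tab$age_years + offset
  m <- fit_age_correction(tab)
  out <- remove_age_effects(tab, m)
  # corrected = offset + fitted-intercept error; differences are exact
  expect_equal(out$shimmer_db - min(out$shimmer_db), offset,
               tolerance = 1e-8)
  # with noisy linear aging, post-correction correlation with age vanishes
  tab$hnr_mean_db <- withr::with_seed(3, {
    -0.2 * tab$age_years + rnorm(nrow(tab), 0, 0.5)
  })
  out2 <- remove_age_effects(tab, fit_age_correction(tab))
  ctrl <- out2[out2$group == "C", ]
  # exact orthogonality: OLS residuals are uncorrelated with the regressor
  # on the fitting (control) set
  expect_lt(abs(cor(ctrl$hnr_mean_db, ctrl$age_years)), 1e-8)
})

test_that("age correction fits on controls but transforms every row", {
  tab <- fixture_feature_table()
  # patients age twice as fast as controls on this feature; the fitted
  # slope must be the control slope
  tab$pitch_sd_hz <- ifelse(tab$group == "C", 1, 4) * tab$age_years
  m <- fit_age_correction(tab)
  expect_equal(m$slopes$slope[m$slopes$feature == "pitch_sd_hz"], 1,
               tolerance = 1e-8)
  out <- remove_age_effects(tab, m)
  b <- out[out$group == "B", ]
  expect_equal(b$pitch_sd_hz, 3 * b$age_years, tolerance = 1e-8)
})

test_that("standardization yields exact zero mean and unit SD", {
  tab <- tibble::tibble(subject_id = "x", jitter_relative_pct = c(1, 2, 3))
  out <- standardize_features(tab, "jitter_relative_pct")
  expect_equal(out$table$jitter_relative_pct, c(-1, 0, 1))
  # idempotent up to numerical tolerance
  twice <- standardize_features(out$table, "jitter_relative_pct")
  expect_equal(twice$table$jitter_relative_pct,
               out$table$jitter_relative_pct, tolerance = 1e-12)
  const <- tibble::tibble(subject_id = "x", shimmer_db = rep(2, 5))
  expect_error(standardize_features(const, "shimmer_db"), "shimmer_db")
})

test_that("PCA by SVD preserves variance and decorrelates scores", {
  tab <- fixture_feature_table()
  tab2 <- remove_age_effects(tab, fit_age_correction(tab))
  std <- standardize_features(tab2)
  pca <- pca_svd(std$table)
  X <- as.matrix(std$table[, phonatory_feature_names])
  S <- as.matrix(pca$scores[, paste0("PC", 1:15)])

  # variance conservation: sum of PC variances = total feature variance
  expect_equal(sum(apply(S, 2, var)), sum(apply(X, 2, var)),
               tolerance = 1e-10)
  # reconstruction X = U S V'
  expect_equal(S %*% t(pca$loadings), X, tolerance = 1e-10,
               ignore_attr = TRUE)
  # score columns mutually uncorrelated
  cc <- cor(S)
  expect_lt(max(abs(cc[upper.tri(cc)])), 1e-10)
  # loadings orthonormal
  expect_equal(t(pca$loadings) %*% pca$loadings, diag(15),
               tolerance = 1e-10, ignore_attr = TRUE)
  # cumulative profile non-decreasing to 1
  expect_true(all(diff(pca$cumulative_variance) >= -1e-12))
  expect_equal(pca$cumulative_variance[15], 1, tolerance = 1e-12)
  # sign convention: largest-|.| loading entry positive
  for (j in 1:15) {
    expect_gt(pca$loadings[which.max(abs(pca$loadings[, j])), j], 0)
  }
})

test_that("variance shares of uncorrelated columns follow their variances", {
  withr::with_seed(10, {
    n <- 4000
    tab <- tibble::tibble(a = rnorm(n, 0, 2), b = rnorm(n, 0, 1))
  })
  # standardize-free path: feed the raw two-column table
  pca <- pca_svd(dplyr::mutate(tab, a = a - mean(a), b = b - mean(b)),
                 features = c("a", "b"))
  expect_equal(pca$explained_variance[1], 0.8, tolerance = 0.05)
  expect_equal(pca$explained_variance[2], 0.2, tolerance = 0.05)
})

test_that("select_pcs keeps metadata, k columns and the variance attribute", {
  tab <- fixture_feature_table()
  std <- standardize_features(tab)
  pca <- pca_svd(std$table)
  s8 <- select_pcs(pca, 8)
  expect_true(all(paste0("PC", 1:8) %in% names(s8)))
  expect_false("PC9" %in% names(s8))
  expect_true(all(c("subject_id", "group", "age_years") %in% names(s8)))
  expect_equal(attr(s8, "cumulative_variance"), pca$cumulative_variance[8])
  # k = p is lossless
  s15 <- select_pcs(pca, 15)
  X <- as.matrix(std$table[, phonatory_feature_names])
  expect_equal(as.matrix(s15[, paste0("PC", 1:15)]) %*% t(pca$loadings),
               X, tolerance = 1e-10, ignore_attr = TRUE)
  expect_error(select_pcs(pca, 16), "k must lie")
  expect_error(select_pcs(pca, 0), "k must lie")
})

test_that("biplot export is internally consistent and oriented by loadings", {
  tab <- fixture_feature_table()
  std <- standardize_features(tab)
  pca <- pca_svd(std$table)
  bp <- biplot_export(pca)
  expect_equal(nrow(bp$loadings), 15)
  expect_named(bp$loadings, c("feature", "Dim1", "Dim2"))
  expect_equal(unname(bp$variance_share),
               pca$explained_variance[1:2], tolerance = 1e-12)
  # group B carries a +2 offset on every feature in this fixture, so its
  # centroid must project on the positive side of the dominant loadings
  agg <- stats::aggregate(bp$scores$Dim1, list(bp$scores$group), mean)
  expect_gt(agg$x[agg$Group.1 == "B"], agg$x[agg$Group.1 == "C"])
})

test_that("subject aggregation averages across vowels", {
  tab <- fixture_feature_table()[1:4, ]
  tab$vowel <- c("a", "e", "a", "e")
  tab$subject_id <- c("P1", "P1", "P2", "P2")
  tab$age_years <- rep(c(50, 60), each = 2)
  tab$sex <- "male"
  tab$group <- rep(c("C", "B"), each = 2)
  out <- aggregate_by_subject(tab)
  expect_equal(nrow(out), 2)
  expect_equal(out$jitter_relative_pct[out$subject_id == "P1"],
               mean(tab$jitter_relative_pct[1:2]))
})
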