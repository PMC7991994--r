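test_that("glottal_spec validates its invariants", {
  expect_error(glottal_spec(f0_hz = -1), "positive")
  expect_error(glottal_spec(duration_s = 0), "positive")
  expect_error(glottal_spec(jitter_frac = -0.01), "non-negative")
  expect_error(glottal_spec(f0_hz = 150, formant_freqs_hz = c(700, 20000),
                            sample_rate_hz = 44100), "4x")
  expect_error(glottal_spec(hnr_db = 150), "not reachable")
})

test_that("waveform generation is deterministic and rejects inverted cycles", {
  gs <- glottal_spec(f0_hz = 120, duration_s = 0.5, jitter_frac = 0.02,
                     shimmer_frac = 0.05, hnr_db = 15, seed = 9)
  a <- generate_glottal_waveform(gs)
  b <- generate_glottal_waveform(gs)
  expect_identical(a$samples, b$samples)
  expect_identical(a$ground_truth, b$ground_truth)
  expect_error(
    generate_glottal_waveform(glottal_spec(jitter_frac = 0.6, seed = 1,
                                           duration_s = 0.5)),
    "non-positive duration")
})

test_that("retained ground truth matches the injected perturbation model", {
  rec <- fixture_perturbed_train()
  gt <- rec$ground_truth
  periods <- gt$period_s[!is.na(gt$period_s)]
  expect_true(all(periods > 0))
  # cycle onsets are consistent with the stored periods
  expect_equal(diff(gt$onset_s), periods, tolerance = 1e-12)
  # ground-truth periods reproduce the closed-form expected jitter within
  # 3 Monte-Carlo standard errors
  d <- abs(diff(periods))
  se <- sd(d) / sqrt(length(d)) / mean(periods) * 100
  measured <- jitter_features(periods)$jitter_relative_pct
  expect_lt(abs(measured - expected_perturbation(0.02)), 3 * se + 1e-9)
})

test_that("expected_perturbation matches brute-force simulation", {
  expect_equal(expected_perturbation(0), 0)
  expect_equal(expected_perturbation(0.02), 2.2567583, tolerance = 1e-6)
  expect_equal(expected_perturbation(0.05), 5.6418958, tolerance = 1e-6)
  # frozen brute-force check: mean |T_i - T_{i-1}| / mean(T) for 1e6 cycles,
  # sigma = 0.02, seed 1 gives 2.2573% (3 SE ~ 0.005%)
  sim <- withr::with_seed(1, {
    t_i <- 1 + rnorm(1e6, 0, 0.02)
    100 * mean(abs(diff(t_i))) / mean(t_i)
  })
  expect_equal(sim, expected_perturbation(0.02), tolerance = 3e-3)
})

test_that("cohort generation yields the study structure deterministically", {
  spec <- cohort_spec(seed = 5, duration_s = 0.4, sample_rate_hz = 16000)
  co <- generate_cohort(spec)
  expect_length(co$recordings, 63 * 5)
  expect_equal(nrow(co$metadata), 315)
  expect_equal(length(unique(co$metadata$subject_id)), 63)
  counts <- dplyr::count(dplyr::distinct(co$metadata,
                                         .data$subject_id, .data$group),
                         .data$group)
  expect_equal(counts$n[match(c("C", "B", "NB"), counts$group)],
               c(18, 14, 31))
  co2 <- generate_cohort(spec)
  expect_identical(co$metadata, co2$metadata)
  expect_identical(co$recordings[[40]]$samples, co2$recordings[[40]]$samples)
})

test_that("cohort invariants are enforced", {
  expect_error(cohort_spec(n_control = 0, n_bulbar = 0, n_nonbulbar = 0),
               "empty")
  bad <- default_effects <- phonatory:::default_group_effects()
  bad$jitter_mean[bad$group == "B"] <- 0.001  # below control mean
  expect_error(cohort_spec(group_effects = bad), "must exceed C")
})

test_that("increasing jitter increases measured jitter; more noise lowers HNR", {
  # ground-truth-level monotonicity, averaged over 20 seeds
  fracs <- c(0.005, 0.02)
  means <- sapply(fracs, function(fr) {
    mean(sapply(1:20, function(s) {
      rec <- generate_glottal_waveform(glottal_spec(
        f0_hz = 100, duration_s = 1, jitter_frac = fr, formant_freqs_hz = NULL,
        hnr_db = Inf, seed = s))
      p <- rec$ground_truth$period_s
      jitter_features(p[!is.na(p)])$jitter_relative_pct
    }))
  })
  expect_gt(means[2], means[1])

  hnrs <- sapply(c(25, 10), function(h) {
    mean(sapply(1:5, function(s) {
      rec <- generate_glottal_waveform(glottal_spec(
        f0_hz = 150, duration_s = 1, hnr_db = h, formant_freqs_hz = NULL,
        seed = s))
      harmonicity(rec)$hnr_mean_db
    }))
  })
  expect_gt(hnrs[1], hnrs[2])
})

test_that("the default group effects give a near-perfect C-vs-B Bayes rate", {
  rate <- cohort_bayes_rate(cohort_spec(), c("C", "B"), n_draws = 50000,
                            seed = 2)
  expect_gte(rate, 0.95)
})
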