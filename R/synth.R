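# Synthetic sustained-vowel generator: glottal pulse trains with controllable
# jitter, shimmer, noise level (HNR) and formant structure, plus whole-cohort
# simulation with group-dependent effect sizes. Provides the ground truth
# against which the analysis stages are validated.

# Neutral formant targets per vowel (Hz); /a/-like default.
vowel_formants <- list(
  a = c(700, 1100, 2600),
  e = c(450, 1900, 2600),
  i = c(300, 2300, 3000),
  o = c(450, 800, 2600),
  u = c(325, 700, 2500)
)

#' Specification of a synthetic glottal waveform
#'
#' Describes one sustained phonation: a raised-cosine glottal pulse train with
#' i.i.d. Gaussian per-cycle period perturbation (jitter), amplitude
#' perturbation (shimmer), additive white noise calibrated to a target
#' harmonics-to-noise ratio, and optional formant resonances.
#'
#' @param f0_hz Target fundamental frequency (Hz).
#' @param duration_s Duration in seconds.
#' @param sample_rate_hz Sampling rate (Hz).
#' @param jitter_frac SD of the per-cycle period perturbation as a fraction of
#'   the mean period.
#' @param shimmer_frac SD of the per-cycle amplitude perturbation as a fraction
#'   of the mean amplitude.
#' @param hnr_db Target harmonics-to-noise ratio in dB; `Inf` for noiseless.
#' @param formant_freqs_hz Optional numeric vector of resonance frequencies
#'   shaping vowel identity, or `NULL` for an unfiltered pulse train.
#' @param open_quotient Fraction of the mean period occupied by the glottal
#'   pulse. The pulse width is fixed at `open_quotient / f0_hz` rather than
#'   rescaled per perturbed cycle so that waveform peaks track the injected
#'   cycle onsets without bias.
#' @param seed Integer RNG seed.
#' @return An object of class `glottal_spec`.
#' @export
glottal_spec <- function(f0_hz = 150, duration_s = 3, sample_rate_hz = 44100,
                         jitter_frac = 0, shimmer_frac = 0, hnr_db = Inf,
                         formant_freqs_hz = vowel_formants$a,
                         open_quotient = 0.6, seed = 1L) {
  if (f0_hz <= 0) abort("f0_hz must be positive")
  if (duration_s <= 0) abort("duration_s must be positive")
  if (jitter_frac < 0 || shimmer_frac < 0) {
    abort("jitter_frac and shimmer_frac must be non-negative")
  }
  top <- max(c(formant_freqs_hz, f0_hz))
  if (sample_rate_hz < 4 * top) {
    abort("sample_rate_hz must be at least 4x the highest formant/f0")
  }
  if (is.finite(hnr_db) && hnr_db > 100) {
    abort("hnr_db above 100 dB is not reachable at this quantization")
  }
  structure(
    list(
      f0_hz = f0_hz, duration_s = duration_s, sample_rate_hz = sample_rate_hz,
      jitter_frac = jitter_frac, shimmer_frac = shimmer_frac, hnr_db = hnr_db,
      formant_freqs_hz = formant_freqs_hz, open_quotient = open_quotient,
      seed = as.integer(seed)
    ),
    class = "glottal_spec"
  )
}

# Cascade of 2-pole resonators (formants), ~90 Hz bandwidth each.
resonator_filter <- function(x, freqs, fs, bandwidth = 90) {
  for (f in freqs) {
    r <- exp(-pi * bandwidth / fs)
    theta <- 2 * pi * f / fs
    a <- c(2 * r * cos(theta), -r^2)
    x <- as.numeric(stats::filter(x, a, method = "recursive"))
  }
  x
}

#' Generate a synthetic sustained-vowel recording
#'
#' Builds a pulse train whose cycle onsets are `T*(1 + eps_i)` apart with
#' `eps_i ~ N(0, jitter_frac)` and cycle amplitudes `1 + delta_i` with
#' `delta_i ~ N(0, shimmer_frac)`, optionally filtered through formant
#' resonators, plus white Gaussian noise scaled so that the realized
#' harmonic-power / noise-power ratio equals `10^(hnr_db / 10)`. The realized
#' per-cycle periods and amplitudes are retained as ground truth.
#'
#' @param spec A [glottal_spec()].
#' @param subject_id,vowel,sex,age_years,group Optional metadata attached to
#'   the returned recording.
#' @return A `voice_recording`: list with `samples`, `sample_rate_hz`,
#'   metadata fields, and a `ground_truth` tibble of cycle onsets, periods and
#'   amplitudes.
#' @export
generate_glottal_waveform <- function(spec, subject_id = "S000", vowel = "a",
                                      sex = "male", age_years = NA_real_,
                                      group = NA_character_) {
  stopifnot(inherits(spec, "glottal_spec"))
  fs <- spec$sample_rate_hz
  tbar <- 1 / spec$f0_hz
  n_samples <- round(spec$duration_s * fs)
  n_cycles <- ceiling(spec$duration_s / tbar) + 2L

  with_seed(spec$seed, {
    eps <- rnorm(n_cycles, 0, spec$jitter_frac)
    if (any(1 + eps <= 0)) {
      abort("jitter_frac so large that a cycle has non-positive duration")
    }
    delta <- rnorm(n_cycles, 0, spec$shimmer_frac)
    if (any(1 + delta <= 0)) {
      abort("shimmer_frac so large that a cycle has non-positive amplitude")
    }
    periods <- tbar * (1 + eps)
    onsets <- c(0, cumsum(periods))[seq_len(n_cycles)]
    amps <- 1 + delta

    width <- spec$open_quotient * tbar
    keep <- onsets + width < spec$duration_s
    onsets <- onsets[keep]; amps <- amps[keep]

    x <- numeric(n_samples)
    for (i in seq_along(onsets)) {
      i0 <- floor(onsets[i] * fs) + 1L
      i1 <- min(ceiling((onsets[i] + width) * fs) + 1L, n_samples)
      if (i0 > n_samples) break
      t_rel <- ((i0:i1) - 1) / fs - onsets[i]
      inside <- t_rel >= 0 & t_rel < width
      x[i0:i1] <- x[i0:i1] +
        amps[i] * 0.5 * (1 - cos(2 * pi * t_rel / width)) * inside
    }

    if (!is.null(spec$formant_freqs_hz)) {
      x <- resonator_filter(x, spec$formant_freqs_hz, fs)
    }
    x <- x - mean(x)

    if (is.finite(spec$hnr_db)) {
      p_harm <- mean(x^2)
      noise_sd <- sqrt(p_harm * 10^(-spec$hnr_db / 10))
      x <- x + rnorm(n_samples, 0, noise_sd)
    }
    x <- x / max(abs(x)) * 0.95
  })

  truth <- tibble(
    onset_s = onsets,
    period_s = c(diff(onsets), NA_real_),
    amplitude = amps
  )

  structure(
    list(
      samples = x, sample_rate_hz = fs,
      subject_id = subject_id, vowel = vowel, sex = sex,
      age_years = age_years, group = group,
      ground_truth = truth, spec = spec
    ),
    class = "voice_recording"
  )
}

#' @export
print.voice_recording <- function(x, ...) {
  cat(sprintf(
    "<voice_recording> %s /%s/ (%s, %s): %.2f s @ %d Hz\n",
    x$subject_id, x$vowel, x$sex, x$group %||% "?",
    length(x$samples) / x$sample_rate_hz, x$sample_rate_hz
  ))
  invisible(x)
}

#' Expected relative perturbation of an i.i.d. Gaussian cycle sequence
#'
#' For i.i.d. Gaussian perturbations with SD `frac` (as a fraction of the
#' mean), the mean absolute consecutive difference has expectation
#' `2 * frac / sqrt(pi)` times the mean, so the relative jitter or shimmer
#' converges to `100 * 2 * frac / sqrt(pi)` percent. Used as the analytic
#' oracle for recovery tests.
#'
#' @param frac Perturbation SD as a fraction of the mean (must be < 0.1 for
#'   the linearization to hold).
#' @return Expected relative perturbation in percent.
#' @export
expected_perturbation <- function(frac) {
  if (any(frac < 0)) abort("frac must be non-negative")
  if (any(frac >= 0.1)) {
    warn("expected_perturbation linearization assumes frac < 0.1")
  }
  100 * 2 * frac / sqrt(pi)
}

default_group_effects <- function() {
  tibble(
    group = c("C", "NB", "B"),
    jitter_mean = c(0.005, 0.010, 0.020),
    jitter_sd = c(0.0015, 0.0050, 0.0060),
    shimmer_mean = c(0.025, 0.045, 0.070),
    shimmer_sd = c(0.008, 0.018, 0.020),
    hnr_mean = c(22, 17, 12),
    hnr_sd = c(2, 4, 3)
  )
}

default_age_dists <- function() {
  tibble(
    group = c("C", "B", "NB"),
    age_mean = c(45.2, 56.8, 58.3),
    age_sd = c(12.2, 12.3, 11.7)
  )
}

#' Specification of a synthetic vowel cohort
#'
#' Emulates the structure of a clinical sustained-vowel study: healthy
#' controls (C), ALS with bulbar involvement (B) and ALS without bulbar
#' involvement (NB), five vowels per subject, group-dependent elevation of
#' jitter/shimmer and depression of HNR in group B, intermediate means with
#' inflated variance in group NB, a younger control group, sex-dependent
#' fundamental frequency, and linear aging of each latent parameter.
#'
#' @param n_control,n_bulbar,n_nonbulbar Subject counts per group.
#' @param vowels Vowel labels (one recording per subject and vowel).
#' @param group_effects Tibble of per-group means/SDs for the latent
#'   `jitter_frac`, `shimmer_frac` and `hnr_db`; see
#'   `phonatory:::default_group_effects()` for the calibrated defaults.
#' @param age_dists Tibble of per-group age mean/SD in years.
#' @param sex_ratio Named vector, fraction of male subjects per group.
#' @param age_slopes Linear aging coefficients added to the latent parameters
#'   (units per year, centred at age 50), applied identically to all groups.
#' @param f0_male,f0_female Mean/SD of the subject fundamental frequency (Hz).
#' @param duration_s,sample_rate_hz Recording duration and sampling rate.
#' @param use_formants Filter pulse trains through vowel-specific formants.
#' @param seed Integer RNG seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_control = 18, n_bulbar = 14, n_nonbulbar = 31,
                        vowels = c("a", "e", "i", "o", "u"),
                        group_effects = default_group_effects(),
                        age_dists = default_age_dists(),
                        sex_ratio = c(C = 9 / 18, B = 3 / 14, NB = 23 / 31),
                        age_slopes = c(jitter_frac = 5e-5,
                                       shimmer_frac = 2e-4,
                                       hnr_db = -0.06),
                        f0_male = c(mean = 120, sd = 15),
                        f0_female = c(mean = 210, sd = 20),
                        duration_s = 3, sample_rate_hz = 44100,
                        use_formants = TRUE, seed = 1L) {
  if (any(c(n_control, n_bulbar, n_nonbulbar) < 0)) {
    abort("group counts must be non-negative")
  }
  if (n_control + n_bulbar + n_nonbulbar == 0) abort("empty cohort")
  ge <- group_effects
  gb <- ge[ge$group == "B", ]; gc_ <- ge[ge$group == "C", ]
  if (gb$jitter_mean < gc_$jitter_mean || gb$shimmer_mean < gc_$shimmer_mean ||
      gb$hnr_mean > gc_$hnr_mean) {
    abort("group B effects must exceed C for jitter/shimmer and be below for HNR")
  }
  if (any(age_dists$age_mean <= 0)) abort("ages must be positive")
  structure(
    list(
      n_control = n_control, n_bulbar = n_bulbar, n_nonbulbar = n_nonbulbar,
      vowels = vowels, group_effects = group_effects, age_dists = age_dists,
      sex_ratio = sex_ratio, age_slopes = age_slopes,
      f0_male = f0_male, f0_female = f0_female,
      duration_s = duration_s, sample_rate_hz = sample_rate_hz,
      use_formants = use_formants, seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

trunc_norm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  x <- rnorm(n, mean, sd)
  bad <- x < lower | x > upper
  while (any(bad)) {
    x[bad] <- rnorm(sum(bad), mean, sd)
    bad <- x < lower | x > upper
  }
  x
}

#' Generate a labelled synthetic cohort of sustained-vowel recordings
#'
#' Draws per-subject ages, sexes and latent phonatory parameters from the
#' group distributions in `spec`, ages them with the linear coefficients in
#' `spec$age_slopes`, and synthesizes one recording per (subject, vowel).
#' Deterministic for a fixed `spec` (including its seed).
#'
#' @param spec A [cohort_spec()].
#' @param include_truth Keep the hidden per-subject latent parameters as
#'   columns of the metadata table.
#' @return A `voice_cohort`: list with `recordings` (list of
#'   `voice_recording`) and `metadata` (tibble; one row per recording).
#' @export
generate_cohort <- function(spec = cohort_spec(), include_truth = FALSE) {
  stopifnot(inherits(spec, "cohort_spec"))
  counts <- c(C = spec$n_control, B = spec$n_bulbar, NB = spec$n_nonbulbar)
  groups <- rep(names(counts), counts)
  n_subj <- length(groups)
  ge <- spec$group_effects
  ad <- spec$age_dists

  subjects <- with_seed(spec$seed, {
    rows <- vector("list", n_subj)
    idx_in_group <- integer(0)
    for (g in names(counts)) {
      ng <- counts[[g]]
      if (ng == 0) next
      n_male <- round(ng * spec$sex_ratio[[g]])
      sexes <- c(rep("male", n_male), rep("female", ng - n_male))
      a <- ad[ad$age_mean > 0 & ad$group == g, ]
      e <- ge[ge$group == g, ]
      ages <- trunc_norm(ng, a$age_mean, a$age_sd, 21, 90)
      jit <- trunc_norm(ng, e$jitter_mean, e$jitter_sd, 5e-4, 0.09)
      shi <- trunc_norm(ng, e$shimmer_mean, e$shimmer_sd, 2e-3, 0.2)
      hnr <- trunc_norm(ng, e$hnr_mean, e$hnr_sd, 2, 40)
      for (i in seq_len(ng)) {
        f0p <- if (sexes[i] == "male") spec$f0_male else spec$f0_female
        f0 <- trunc_norm(1, f0p[["mean"]], f0p[["sd"]],
                         0.6 * f0p[["mean"]], 1.5 * f0p[["mean"]])
        rows[[length(idx_in_group) + 1L]] <- tibble(
          group = g, sex = sexes[i], age_years = round(ages[i], 1),
          latent_jitter = jit[i], latent_shimmer = shi[i],
          latent_hnr = hnr[i], f0_hz = f0
        )
        idx_in_group <- c(idx_in_group, i)
      }
    }
    bind_rows(rows)
  })
  subjects$subject_id <- sprintf("S%03d", seq_len(n_subj))

  # linear aging, centred at 50 years, identical mechanism in every group
  dage <- subjects$age_years - 50
  subjects$latent_jitter <- pmax(
    subjects$latent_jitter + spec$age_slopes[["jitter_frac"]] * dage, 5e-4)
  subjects$latent_shimmer <- pmax(
    subjects$latent_shimmer + spec$age_slopes[["shimmer_frac"]] * dage, 2e-3)
  subjects$latent_hnr <- pmax(
    subjects$latent_hnr + spec$age_slopes[["hnr_db"]] * dage, 2)

  utter <- with_seed(derive_seed(spec$seed, 1), {
    tidyr::crossing(subjects, vowel = spec$vowels) |>
      arrange(.data$subject_id, .data$vowel) |>
      mutate(
        utt_jitter = pmax(.data$latent_jitter +
                            rnorm(n(), 0, 0.15 * .data$latent_jitter), 5e-4),
        utt_shimmer = pmax(.data$latent_shimmer +
                             rnorm(n(), 0, 0.15 * .data$latent_shimmer), 2e-3),
        utt_hnr = pmax(.data$latent_hnr + rnorm(n(), 0, 0.5), 2),
        utt_f0 = pmax(.data$f0_hz + rnorm(n(), 0, 4), 60),
        rec_seed = sample.int(2147483646, n())
      )
  })

  recordings <- vector("list", nrow(utter))
  for (i in seq_len(nrow(utter))) {
    u <- utter[i, ]
    gs <- glottal_spec(
      f0_hz = u$utt_f0, duration_s = spec$duration_s,
      sample_rate_hz = spec$sample_rate_hz,
      jitter_frac = u$utt_jitter, shimmer_frac = u$utt_shimmer,
      hnr_db = u$utt_hnr,
      formant_freqs_hz = if (spec$use_formants) vowel_formants[[u$vowel]] else NULL,
      seed = u$rec_seed
    )
    recordings[[i]] <- generate_glottal_waveform(
      gs, subject_id = u$subject_id, vowel = u$vowel, sex = u$sex,
      age_years = u$age_years, group = u$group
    )
  }

  meta_cols <- c("subject_id", "vowel", "sex", "age_years", "group")
  truth_cols <- c("latent_jitter", "latent_shimmer", "latent_hnr", "f0_hz",
                  "utt_jitter", "utt_shimmer", "utt_hnr", "utt_f0")
  metadata <- utter[, c(meta_cols, if (include_truth) truth_cols)]

  structure(list(recordings = recordings, metadata = metadata),
            class = "voice_cohort")
}

#' @export
print.voice_cohort <- function(x, ...) {
  cat(sprintf("<voice_cohort> %d recordings, %d subjects\n",
              length(x$recordings), length(unique(x$metadata$subject_id))))
  print(count(x$metadata, .data$group))
  invisible(x)
}

#' Monte-Carlo Bayes rate of the cohort's latent group distributions
#'
#' Estimates the accuracy of the optimal (Bayes) classifier that sees the
#' latent (jitter, shimmer, HNR) triple of a subject, under the generating
#' group distributions of `spec` and equal priors. Serves as the oracle for
#' separability checks: no downstream classifier on extracted features can
#' beat this rate except through estimation noise or subject leakage.
#'
#' @param spec A [cohort_spec()].
#' @param groups The two groups to separate.
#' @param n_draws Monte-Carlo sample size.
#' @param seed RNG seed.
#' @return Estimated Bayes accuracy as a fraction in (0, 1).
#' @export
cohort_bayes_rate <- function(spec = cohort_spec(), groups = c("C", "B"),
                              n_draws = 200000, seed = 1L) {
  ge <- spec$group_effects
  e1 <- ge[ge$group == groups[1], ]
  e2 <- ge[ge$group == groups[2], ]
  logdens <- function(x, e) {
    stats::dnorm(x[, 1], e$jitter_mean, e$jitter_sd, log = TRUE) +
      stats::dnorm(x[, 2], e$shimmer_mean, e$shimmer_sd, log = TRUE) +
      stats::dnorm(x[, 3], e$hnr_mean, e$hnr_sd, log = TRUE)
  }
  with_seed(seed, {
    half <- n_draws %/% 2
    draw <- function(e, m) {
      cbind(rnorm(m, e$jitter_mean, e$jitter_sd),
            rnorm(m, e$shimmer_mean, e$shimmer_sd),
            rnorm(m, e$hnr_mean, e$hnr_sd))
    }
    x1 <- draw(e1, half); x2 <- draw(e2, half)
    correct1 <- mean(logdens(x1, e1) >= logdens(x1, e2))
    correct2 <- mean(logdens(x2, e2) > logdens(x2, e1))
    (correct1 + correct2) / 2
  })
}
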