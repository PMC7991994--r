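# Shared fixtures, generated once per test run. All audio is synthesized in
# code; nothing is stored on disk.

fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = fixture_env)) {
    assign(key, force(expr), envir = fixture_env)
  }
  get(key, envir = fixture_env)
}

# clean unfiltered 100 Hz pulse train, 3 s
fixture_clean_train <- function() memo("clean_train", {
  generate_glottal_waveform(glottal_spec(
    f0_hz = 100, duration_s = 3, jitter_frac = 0, shimmer_frac = 0,
    hnr_db = Inf, formant_freqs_hz = NULL, seed = 101
  ))
})

# jittered/shimmered unfiltered train with retained ground truth
fixture_perturbed_train <- function() memo("perturbed_train", {
  generate_glottal_waveform(glottal_spec(
    f0_hz = 100, duration_s = 4, jitter_frac = 0.02, shimmer_frac = 0.03,
    hnr_db = Inf, formant_freqs_hz = NULL, seed = 202
  ))
})

fixture_tone <- function(freq = 150, fs = 44100, dur = 2, sex = "male") {
  tt <- seq(0, dur, by = 1 / fs)
  voice_recording(sin(2 * pi * freq * tt), fs, sex = sex)
}

# small feature table with known aging and group offsets, for the
# preprocessing stages (no audio involved)
fixture_feature_table <- function(n_per_group = 20, seed = 33) {
  withr::with_seed(seed, {
    groups <- rep(c("C", "B", "NB"), each = n_per_group)
    n <- length(groups)
    age <- round(runif(n, 30, 80), 1)
    base <- matrix(rnorm(n * 15), n, 15)
    tab <- tibble::tibble(
      subject_id = sprintf("T%03d", seq_len(n)),
      vowel = "a", sex = "male", age_years = age, group = groups
    )
    for (j in seq_along(phonatory_feature_names)) {
      tab[[phonatory_feature_names[j]]] <- base[, j] + 0.1 * j * age +
        ifelse(groups == "B", 2, 0)
    }
    tab
  })
}

# ready-made PC score table with separable groups (no audio), subject ids
fixture_score_table <- function(n_c = 18, n_b = 14, n_nb = 31, sep = 3,
                                n_pcs = 8, seed = 44) {
  withr::with_seed(seed, {
    groups <- rep(c("C", "B", "NB"), c(n_c, n_b, n_nb))
    subj <- sprintf("S%03d", seq_along(groups))
    meta <- tidyr::crossing(
      tibble::tibble(subject_id = subj, group = groups),
      vowel = c("a", "e", "i", "o", "u")
    )
    shift <- c(C = -sep / 2, B = sep / 2, NB = 0.15 * sep)[meta$group]
    pcs <- sapply(seq_len(n_pcs), function(j) {
      rnorm(nrow(meta)) + if (j <= 2) shift else 0
    })
    colnames(pcs) <- paste0("PC", seq_len(n_pcs))
    dplyr::bind_cols(meta, tibble::as_tibble(pcs))
  })
}
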