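# Orchestration of the full per-utterance feature set: trimming, pitch
# tracking, cycle extraction, the jitter/shimmer families and frame-based
# HNR, yielding the 15 canonical phonatory features.

#' Extract the 15 phonatory features from one recording
#'
#' Runs trim -> pitch track -> cycle extraction -> jitter/shimmer ->
#' harmonicity -> pitch statistics and assembles one row with the 15
#' canonical features. "Undefined" results propagate as `NA`; they are never
#' silently replaced.
#'
#' @param rec A `voice_recording` (its `sex` field selects the pitch
#'   defaults).
#' @param trim Trim to the phonated span first (default `TRUE`).
#' @param pitch A [pitch_settings()] override.
#' @param perturbation A [perturbation_settings()] override.
#' @param harmonic A [harmonicity_settings()] override.
#' @param energy_frac Threshold passed to [trim_phonation()].
#' @return One-row tibble: `subject_id`, `vowel`, `sex`, `age_years`,
#'   `group`, then the 15 columns of [phonatory_feature_names].
#' @export
extract_features <- function(rec, trim = TRUE, pitch = NULL,
                             perturbation = perturbation_settings(),
                             harmonic = harmonicity_settings(),
                             energy_frac = 0.1) {
  stopifnot(inherits(rec, "voice_recording"))
  if (trim) rec <- trim_phonation(rec, energy_frac = energy_frac)

  track <- track_pitch(rec, pitch)
  pstats <- pitch_stats(track)
  cycles <- extract_cycles(rec, track)
  jit <- jitter_features(cycles, perturbation)
  shim <- if (nrow(cycles) >= 2) {
    shimmer_features(cycles, perturbation)
  } else {
    tibble(shimmer_relative_pct = NA_real_, shimmer_db = NA_real_,
           shimmer_apq3_pct = NA_real_, shimmer_apq5_pct = NA_real_,
           shimmer_apq11_pct = NA_real_)
  }
  harm <- harmonicity(rec, harmonic)

  bind_cols(
    tibble(subject_id = rec$subject_id, vowel = rec$vowel, sex = rec$sex,
           age_years = rec$age_years, group = rec$group),
    jit, shim, pstats,
    tibble(hnr_mean_db = harm$hnr_mean_db, hnr_sd_db = harm$hnr_sd_db)
  )[, c("subject_id", "vowel", "sex", "age_years", "group",
        phonatory_feature_names)]
}

#' Extract features for every recording of a cohort
#'
#' @param cohort A `voice_cohort` from [generate_cohort()], or a plain list
#'   of `voice_recording` objects.
#' @param ... Passed to [extract_features()].
#' @param progress Print a dot every 25 recordings.
#' @return Tibble with one row per recording.
#' @export
extract_cohort_features <- function(cohort, ..., progress = FALSE) {
  recs <- if (inherits(cohort, "voice_cohort")) cohort$recordings else cohort
  out <- vector("list", length(recs))
  for (i in seq_along(recs)) {
    out[[i]] <- extract_features(recs[[i]], ...)
    if (progress && i %% 25 == 0) cat(".")
  }
  if (progress) cat("\n")
  bind_rows(out)
}

#' Write a feature table to CSV
#'
#' Undefined values are serialized as empty cells.
#'
#' @param features Tibble from [extract_cohort_features()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(features, path) {
  readr::write_csv(features, path, na = "")
  invisible(path)
}
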