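# Autocorrelation pitch tracking for sustained vowels, with sex-specific
# search ranges, and descriptive pitch statistics over voiced frames.

#' Pitch analysis settings
#'
#' Defaults follow the conventional sex-specific ranges for sustained-vowel
#' analysis: floor/ceiling 60/300 Hz and time step 0.0125 s for males,
#' 100/500 Hz and 0.0075 s for females.
#'
#' @param sex `"male"` or `"female"`; selects the defaults.
#' @param pitch_floor_hz,pitch_ceiling_hz Search range (Hz).
#' @param time_step_s Frame hop (s).
#' @param silence_threshold Frames whose peak amplitude falls below this
#'   fraction of the global maximum are marked unvoiced.
#' @return An object of class `pitch_settings`.
#' @export
pitch_settings <- function(sex = c("male", "female"),
                           pitch_floor_hz = NULL, pitch_ceiling_hz = NULL,
                           time_step_s = NULL, silence_threshold = 0.1) {
  sex <- match.arg(sex)
  defs <- if (sex == "male") {
    list(floor = 60, ceiling = 300, step = 0.0125)
  } else {
    list(floor = 100, ceiling = 500, step = 0.0075)
  }
  s <- list(
    pitch_floor_hz = pitch_floor_hz %||% defs$floor,
    pitch_ceiling_hz = pitch_ceiling_hz %||% defs$ceiling,
    time_step_s = time_step_s %||% defs$step,
    silence_threshold = silence_threshold
  )
  if (s$pitch_floor_hz <= 0 || s$pitch_ceiling_hz <= s$pitch_floor_hz) {
    abort("need 0 < pitch floor < pitch ceiling")
  }
  if (s$time_step_s <= 0) abort("time_step_s must be positive")
  if (s$silence_threshold <= 0 || s$silence_threshold >= 1) {
    abort("silence_threshold must lie in (0, 1)")
  }
  structure(s, class = "pitch_settings")
}

#' Track fundamental frequency by windowed autocorrelation
#'
#' Each frame is Hann-windowed, its normalized autocorrelation is corrected
#' for the window taper, and the fundamental is taken as the smallest-lag
#' strong local maximum (strong = within 85% of the best peak), refined by
#' parabolic interpolation. Frames are marked unvoiced when their amplitude
#' is below the silence threshold, when no credible peak exists, or when the
#' estimated fundamental falls outside `[floor, ceiling]` — out-of-range
#' pitch is not estimated, it is reported as unvoiced.
#'
#' @param rec A `voice_recording`.
#' @param settings A [pitch_settings()]; defaults follow `rec$sex`.
#' @return A `pitch_track` tibble with `time_s` and `f0_hz` (`NA` when
#'   unvoiced), carrying the settings as an attribute.
#' @export
track_pitch <- function(rec, settings = NULL) {
  stopifnot(inherits(rec, "voice_recording"))
  settings <- settings %||% pitch_settings(rec$sex)
  x <- rec$samples
  fs <- rec$sample_rate_hz
  n <- length(x)
  if (n / fs < 1 / settings$pitch_floor_hz) {
    abort("recording shorter than one analysis window")
  }
  win_s <- min(3 / settings$pitch_floor_hz, n / fs)
  win_n <- max(round(win_s * fs), 32L)
  win_n <- min(win_n, n)
  hop_n <- max(round(settings$time_step_s * fs), 1L)

  starts <- seq(1L, n - win_n + 1L, by = hop_n)
  if (length(starts) == 0) starts <- 1L
  global_max <- max(abs(x))
  lag_min <- max(2L, floor(fs / (4 * settings$pitch_ceiling_hz)))
  lag_max <- ceiling(fs / settings$pitch_floor_hz)

  f0 <- rep(NA_real_, length(starts))
  for (j in seq_along(starts)) {
    xi <- x[starts[j]:(starts[j] + win_n - 1L)]
    if (max(abs(xi)) < settings$silence_threshold * global_max) next
    pk <- acf_peak(xi, fs, lag_min, lag_max)
    if (is.null(pk) || pk$r < 0.35) next
    cand <- fs / pk$lag
    if (cand >= settings$pitch_floor_hz && cand <= settings$pitch_ceiling_hz) {
      f0[j] <- cand
    }
  }
  out <- tibble(
    time_s = (starts - 1L + win_n / 2) / fs,
    f0_hz = f0
  )
  attr(out, "settings") <- settings
  attr(out, "sample_rate_hz") <- fs
  class(out) <- c("pitch_track", class(out))
  out
}

#' Pitch statistics over voiced frames
#'
#' Mean, sample standard deviation (n - 1 denominator), minimum and maximum
#' of the voiced fundamental-frequency estimates. With no voiced frame all
#' four are undefined (`NA`); with a single voiced frame the SD is `NA`.
#'
#' @param track A `pitch_track` from [track_pitch()].
#' @return One-row tibble: `pitch_mean_hz`, `pitch_sd_hz`, `pitch_min_hz`,
#'   `pitch_max_hz`.
#' @export
pitch_stats <- function(track) {
  f0 <- track$f0_hz[!is.na(track$f0_hz)]
  if (length(f0) == 0) {
    return(tibble(pitch_mean_hz = NA_real_, pitch_sd_hz = NA_real_,
                  pitch_min_hz = NA_real_, pitch_max_hz = NA_real_))
  }
  tibble(
    pitch_mean_hz = mean(f0),
    pitch_sd_hz = sample_sd(f0),
    pitch_min_hz = min(f0),
    pitch_max_hz = max(f0)
  )
}
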