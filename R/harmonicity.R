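# Frame-based harmonics-to-noise ratio from the second local maximum of the
# normalized autocorrelation.

#' Harmonicity analysis settings
#'
#' @param time_step_s Frame hop (default 0.01 s).
#' @param pitch_floor_hz Lowest admissible fundamental (default 60 Hz,
#'   regardless of sex); also sets the window length via `periods_per_window`.
#' @param pitch_ceiling_hz Highest admissible fundamental for the peak search
#'   (default 500 Hz, covering both sexes).
#' @param silence_threshold Frames whose peak amplitude falls below this
#'   fraction of the global maximum are skipped as silent (default 0.1).
#' @param periods_per_window Window length in periods of the pitch floor
#'   (default 4.5, i.e. 75 ms at 60 Hz).
#' @return An object of class `harmonicity_settings`.
#' @export
harmonicity_settings <- function(time_step_s = 0.01, pitch_floor_hz = 60,
                                 pitch_ceiling_hz = 500,
                                 silence_threshold = 0.1,
                                 periods_per_window = 4.5) {
  vals <- c(time_step_s, pitch_floor_hz, pitch_ceiling_hz, silence_threshold,
            periods_per_window)
  if (any(vals <= 0)) abort("all harmonicity settings must be positive")
  structure(
    list(time_step_s = time_step_s, pitch_floor_hz = pitch_floor_hz,
         pitch_ceiling_hz = pitch_ceiling_hz,
         silence_threshold = silence_threshold,
         periods_per_window = periods_per_window),
    class = "harmonicity_settings"
  )
}

#' Harmonics-to-noise ratio from an autocorrelation peak
#'
#' `HNR = 10 * log10(r / (1 - r))` where `r` is the second local maximum of
#' the normalized autocorrelation (the first being lag 0). `r = 0.5` maps to
#' exactly 0 dB; `r` is clamped below 1 by `eps` to keep the log finite.
#'
#' @param r Autocorrelation peak value(s) in (0, 1).
#' @param eps Clamp distance from 1 (default `1e-6`, capping HNR at 60 dB).
#' @return HNR in dB.
#' @export
hnr_from_r <- function(r, eps = 1e-6) {
  r <- pmin(r, 1 - eps)
  10 * log10(r / (1 - r))
}

#' Frame-based harmonics-to-noise ratio of a recording
#'
#' Each frame is mean-removed, Hann-windowed and autocorrelated; the
#' autocorrelation is divided by the analytic autocorrelation of the window
#' itself (taper correction), the second local maximum `r(tau)` is located
#' within the admissible pitch range and refined parabolically, and the
#' frame HNR is `10 * log10(r / (1 - r))`. Silent frames and frames with no
#' positive peak are skipped. The summary statistics are the sample mean and
#' SD over retained frames.
#'
#' @param rec A `voice_recording`.
#' @param settings A [harmonicity_settings()].
#' @return List with `hnr_mean_db`, `hnr_sd_db` (NA when no/one frame is
#'   retained) and `frames`, a tibble of `time_s`, `r_tau`, `hnr_db`.
#' @export
harmonicity <- function(rec, settings = harmonicity_settings()) {
  stopifnot(inherits(rec, "voice_recording"))
  x <- rec$samples
  fs <- rec$sample_rate_hz
  n <- length(x)
  win_n <- round(settings$periods_per_window / settings$pitch_floor_hz * fs)
  hop_n <- max(round(settings$time_step_s * fs), 1L)
  empty <- tibble(time_s = numeric(0), r_tau = numeric(0),
                  hnr_db = numeric(0))
  if (n < win_n) {
    return(list(hnr_mean_db = NA_real_, hnr_sd_db = NA_real_, frames = empty))
  }
  starts <- seq(1L, n - win_n + 1L, by = hop_n)
  global_max <- max(abs(x))
  lag_min <- max(2L, floor(fs / settings$pitch_ceiling_hz))
  lag_max <- ceiling(fs / settings$pitch_floor_hz)

  times <- r_vals <- numeric(0)
  for (s0 in starts) {
    xi <- x[s0:(s0 + win_n - 1L)]
    if (max(abs(xi)) < settings$silence_threshold * global_max) next
    pk <- acf_peak(xi, fs, lag_min, lag_max)
    if (is.null(pk) || pk$r <= 0) next
    times <- c(times, (s0 - 1L + win_n / 2) / fs)
    r_vals <- c(r_vals, min(pk$r, 1 - 1e-6))
  }
  frames <- tibble(time_s = times, r_tau = r_vals,
                   hnr_db = hnr_from_r(r_vals))
  list(
    hnr_mean_db = if (nrow(frames) > 0) mean(frames$hnr_db) else NA_real_,
    hnr_sd_db = sample_sd(frames$hnr_db),
    frames = frames
  )
}
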