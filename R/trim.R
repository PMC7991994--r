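#' Trim a recording to its phonated span
#'
#' Locates the contiguous span where the short-time RMS energy exceeds
#' `energy_frac` times the global maximum RMS and returns the recording cut
#' to that span. This automates the boundary-marking step that is done by
#' hand with oscillograms/spectrograms in clinical practice: the onset of
#' periodic energy opens the span and its marked decrease closes it.
#' Idempotent on already-trimmed steady phonations.
#'
#' @param rec A `voice_recording`.
#' @param energy_frac Fraction of the maximum short-time RMS that counts as
#'   phonation.
#' @param frame_s,hop_s Analysis frame length and hop (s).
#' @return The trimmed `voice_recording`; ground-truth cycle times, if
#'   present, are shifted to the new origin.
#' @export
trim_phonation <- function(rec, energy_frac = 0.1, frame_s = 0.03,
                           hop_s = 0.01) {
  stopifnot(inherits(rec, "voice_recording"))
  if (energy_frac <= 0 || energy_frac >= 1) {
    abort("energy_frac must lie in (0, 1)")
  }
  x <- rec$samples
  fs <- rec$sample_rate_hz
  win <- max(round(frame_s * fs), 8L)
  hop <- max(round(hop_s * fs), 1L)
  fr <- frame_rms(x, win, hop)
  thr <- energy_frac * max(fr$rms)
  if (max(fr$rms) == 0 || !any(fr$rms >= thr & fr$rms > 0)) {
    abort("no phonation detected")
  }
  run <- longest_true_run(fr$rms >= thr)
  if (is.null(run)) abort("no phonation detected")
  a <- fr$start[run[1]]
  b <- fr$end[run[2]]
  out <- rec
  out$samples <- x[a:b]
  if (!is.null(rec$ground_truth)) {
    t0 <- (a - 1) / fs
    t1 <- b / fs
    gt <- rec$ground_truth
    gt <- gt[gt$onset_s >= t0 & gt$onset_s < t1, , drop = FALSE]
    gt$onset_s <- gt$onset_s - t0
    out$ground_truth <- gt
  }
  attr(out, "trim_span_s") <- c((a - 1) / fs, b / fs)
  out
}
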