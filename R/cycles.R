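# Glottal cycle extraction: waveform-peak marks guided by the pitch track,
# yielding the per-cycle fundamental periods T_i and peak-to-peak amplitudes
# A_i on which the jitter and shimmer families operate.

#' Perturbation analysis settings
#'
#' @param period_floor_s,period_ceiling_s Minimum and maximum cycle durations
#'   considered in the analysis (defaults 0.002 s and 0.025 s).
#' @param max_period_factor Largest allowed ratio between the durations of
#'   two consecutive cycles (default 1.3); pairs exceeding it are excluded.
#' @return An object of class `perturbation_settings`.
#' @export
perturbation_settings <- function(period_floor_s = 0.002,
                                  period_ceiling_s = 0.025,
                                  max_period_factor = 1.3) {
  if (period_floor_s <= 0 || period_ceiling_s <= period_floor_s) {
    abort("need 0 < period floor < period ceiling")
  }
  if (max_period_factor <= 1) abort("max_period_factor must exceed 1")
  structure(
    list(period_floor_s = period_floor_s, period_ceiling_s = period_ceiling_s,
         max_period_factor = max_period_factor),
    class = "perturbation_settings"
  )
}

#' Extract glottal cycles from a recording
#'
#' Cycle marks are placed at dominant waveform extrema: starting from the
#' strongest peak, the expected location of each neighbouring peak is
#' predicted from the local fundamental frequency of `track` and the actual
#' extremum is searched within +/- 30% of a period, then refined to
#' sub-sample precision by parabolic interpolation. Periods are successive
#' mark differences. The peak-to-peak amplitude of cycle i is max - min of
#' the samples between the midpoints towards the neighbouring marks, so each
#' amplitude window contains exactly one excitation peak.
#'
#' @param rec A `voice_recording`.
#' @param track A `pitch_track`; computed from `rec` if omitted.
#' @return A `cycle_sequence` tibble with `time_s` (cycle onset marks),
#'   `period_s` and `peak_amplitude`; zero rows when no voiced frames or
#'   fewer than two marks are found.
#' @export
extract_cycles <- function(rec, track = NULL) {
  stopifnot(inherits(rec, "voice_recording"))
  track <- track %||% track_pitch(rec)
  empty <- tibble(time_s = numeric(0), period_s = numeric(0),
                  peak_amplitude = numeric(0))
  class(empty) <- c("cycle_sequence", class(empty))

  voiced <- !is.na(track$f0_hz)
  if (!any(voiced)) return(empty)
  x <- rec$samples
  fs <- rec$sample_rate_hz
  n <- length(x)

  # local period (samples) at an arbitrary sample index, from the track
  vt <- track$time_s[voiced]
  vf <- track$f0_hz[voiced]
  f0_med <- median(vf)
  local_f0 <- function(i) {
    t <- (i - 1) / fs
    j <- which.min(abs(vt - t))
    if (abs(vt[j] - t) > 0.05) f0_med else vf[j]
  }

  # polarity: analyse the signal with its dominant extremum made positive
  anchor <- which.max(abs(x))
  y <- x * sign(x[anchor])
  peak_floor <- 0.05 * y[anchor]

  march <- function(from, dir) {
    marks <- integer(0)
    pos <- from
    repeat {
      per_n <- fs / local_f0(pos)
      center <- pos + dir * per_n
      lo <- round(center - 0.3 * per_n)
      hi <- round(center + 0.3 * per_n)
      if (lo < 1 || hi > n) break
      seg <- y[lo:hi]
      m <- lo + which.max(seg) - 1L
      if (y[m] < peak_floor) break
      marks <- c(marks, m)
      pos <- m
    }
    marks
  }

  marks <- sort(c(rev(march(anchor, -1)), anchor, march(anchor, +1)))
  if (length(marks) < 2) return(empty)

  times <- vapply(marks, function(m) {
    ref <- parabolic_refine(y, m)
    (m - 1 + ref$offset) / fs
  }, numeric(1))

  periods <- diff(times)
  n_cyc <- length(periods)

  # amplitude windows: midpoint-to-midpoint around mark i
  mids <- (marks[-length(marks)] + marks[-1]) / 2
  left <- c(max(1, round(marks[1] - (marks[2] - marks[1]) / 2)),
            round(mids))
  right <- c(round(mids), min(n, round(marks[length(marks)] +
                                         (marks[length(marks)] -
                                            marks[length(marks) - 1]) / 2)))
  amp <- vapply(seq_len(n_cyc), function(i) {
    seg <- x[left[i]:right[i]]
    max(seg) - min(seg)
  }, numeric(1))

  out <- tibble(time_s = times[seq_len(n_cyc)], period_s = periods,
                peak_amplitude = amp)
  attr(out, "n_marks") <- length(marks)
  class(out) <- c("cycle_sequence", class(out))
  out
}

#' Validity mask for consecutive cycle pairs
#'
#' A pair of consecutive periods `(T_i, T_{i+1})` is valid iff both lie
#' within `[period_floor, period_ceiling]` and the period factor
#' `max(T_{i+1}/T_i, T_i/T_{i+1})` does not exceed `max_period_factor`.
#' Every excluded term lowers the effective cycle count by one; downstream
#' statistics become undefined when fewer than two usable cycles remain.
#'
#' @param cycles A `cycle_sequence` (or numeric vector of periods in s).
#' @param settings A [perturbation_settings()].
#' @return Logical vector of length `N - 1`, one entry per consecutive pair,
#'   with the effective cycle count as attribute `effective_n`.
#' @export
valid_pair_mask <- function(cycles, settings = perturbation_settings()) {
  periods <- if (is.numeric(cycles)) cycles else cycles$period_s
  n <- length(periods)
  if (n < 2) {
    m <- logical(0)
    attr(m, "effective_n") <- n
    return(m)
  }
  in_range <- periods >= settings$period_floor_s &
    periods <= settings$period_ceiling_s
  t1 <- periods[-n]
  t2 <- periods[-1]
  factor_ok <- pmax(t1 / t2, t2 / t1) <= settings$max_period_factor
  mask <- in_range[-n] & in_range[-1] & factor_ok
  attr(mask, "effective_n") <- sum(mask) + as.integer(any(mask))
  mask
}
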