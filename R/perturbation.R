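# The jitter and shimmer perturbation families. All statistics operate on
# the per-cycle periods T_i and peak-to-peak amplitudes A_i of a
# cycle_sequence and share the same exclusion rules: consecutive-difference
# statistics drop pairs that violate the period floor/ceiling or the maximum
# period factor; windowed quotients (rap, ppq5, apq3/5/11) use only windows
# that fit entirely inside the sequence with every period in range. When the
# rules leave fewer than two usable cycles (or no complete window) the
# result is the distinguished value "undefined", carried as NA.

perturbation_guard <- function(periods, settings) {
  n <- length(periods)
  in_range <- periods >= settings$period_floor_s &
    periods <= settings$period_ceiling_s
  list(
    n = n,
    in_range = in_range,
    mask = valid_pair_mask(periods, settings),
    mean_period = if (any(in_range)) mean(periods[in_range]) else NA_real_
  )
}

# mean |v_i - centered-window-mean| over windows of width `width` whose
# periods are all in range; NA when no window qualifies.
window_quotient <- function(values, in_range, width) {
  n <- length(values)
  half <- (width - 1) / 2
  idx <- seq_len(n)
  idx <- idx[idx > half & idx <= n - half]
  terms <- c()
  for (i in idx) {
    w <- (i - half):(i + half)
    if (all(in_range[w])) {
      terms <- c(terms, abs(values[i] - mean(values[w])))
    }
  }
  if (length(terms) == 0) NA_real_ else mean(terms)
}

#' Jitter features of a cycle sequence
#'
#' * `jitter_absolute_s`: mean absolute difference between consecutive
#'   periods (s), over valid pairs.
#' * `jitter_relative_pct`: the same divided by the mean period, in percent.
#' * `jitter_rap_pct`: relative average perturbation — mean absolute
#'   difference between a period and the mean of it and its two neighbours,
#'   divided by the mean period.
#' * `jitter_ppq5_pct`: five-point period perturbation quotient, the
#'   analogous statistic with a centred 5-period window.
#'
#' @param cycles A `cycle_sequence` (or numeric vector of periods in s).
#' @param settings A [perturbation_settings()].
#' @return One-row tibble with the four jitter variants; `NA` marks
#'   "undefined" results.
#' @export
jitter_features <- function(cycles, settings = perturbation_settings()) {
  periods <- if (is.numeric(cycles)) cycles else cycles$period_s
  und <- tibble(jitter_absolute_s = NA_real_, jitter_relative_pct = NA_real_,
                jitter_rap_pct = NA_real_, jitter_ppq5_pct = NA_real_)
  g <- perturbation_guard(periods, settings)
  if (g$n < 2 || is.na(g$mean_period)) return(und)

  diffs <- abs(diff(periods))[g$mask]
  jabs <- if (length(diffs) >= 1) mean(diffs) else NA_real_
  jrel <- if (is.na(jabs)) NA_real_ else 100 * jabs / g$mean_period
  rap_num <- window_quotient(periods, g$in_range, 3)
  ppq5_num <- window_quotient(periods, g$in_range, 5)

  tibble(
    jitter_absolute_s = jabs,
    jitter_relative_pct = jrel,
    jitter_rap_pct = 100 * rap_num / g$mean_period,
    jitter_ppq5_pct = 100 * ppq5_num / g$mean_period
  )
}

#' Shimmer features of a cycle sequence
#'
#' * `shimmer_db`: mean absolute base-10 logarithm of the ratio of
#'   consecutive peak-to-peak amplitudes, times 20.
#' * `shimmer_relative_pct`: mean absolute difference between consecutive
#'   amplitudes divided by the mean amplitude, in percent.
#' * `shimmer_apq3_pct`, `shimmer_apq5_pct`, `shimmer_apq11_pct`: 3-, 5- and
#'   11-point amplitude perturbation quotients (centred windows).
#'
#' Pair validity follows the same period-based mask as jitter.
#'
#' @param cycles A `cycle_sequence`, or a list/tibble with `period_s` and
#'   `peak_amplitude`.
#' @param settings A [perturbation_settings()].
#' @return One-row tibble with the five shimmer variants; `NA` marks
#'   "undefined" results.
#' @export
shimmer_features <- function(cycles, settings = perturbation_settings()) {
  periods <- cycles$period_s
  amps <- cycles$peak_amplitude
  und <- tibble(shimmer_relative_pct = NA_real_, shimmer_db = NA_real_,
                shimmer_apq3_pct = NA_real_, shimmer_apq5_pct = NA_real_,
                shimmer_apq11_pct = NA_real_)
  g <- perturbation_guard(periods, settings)
  if (g$n < 2 || is.na(g$mean_period)) return(und)
  if (any(amps[g$in_range] <= 0)) {
    abort("non-positive peak amplitude: shimmer(dB) undefined on log scale")
  }
  mean_amp <- mean(amps[g$in_range])

  da <- abs(diff(amps))[g$mask]
  dlog <- abs(20 * log10(amps[-1] / amps[-g$n]))[g$mask]
  srel <- if (length(da) >= 1) 100 * mean(da) / mean_amp else NA_real_
  sdb <- if (length(dlog) >= 1) mean(dlog) else NA_real_

  tibble(
    shimmer_relative_pct = srel,
    shimmer_db = sdb,
    shimmer_apq3_pct = 100 * window_quotient(amps, g$in_range, 3) / mean_amp,
    shimmer_apq5_pct = 100 * window_quotient(amps, g$in_range, 5) / mean_amp,
    shimmer_apq11_pct = 100 * window_quotient(amps, g$in_range, 11) / mean_amp
  )
}
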