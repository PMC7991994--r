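# Independent brute-force oracles for the perturbation statistics: plain
# loop transcriptions of the printed equations, kept deliberately separate
# from the package implementation.

oracle_pair_valid <- function(periods, floor = 0.002, ceiling = 0.025,
                              maxfac = 1.3) {
  n <- length(periods)
  ok <- logical(max(n - 1, 0))
  for (i in seq_len(n - 1)) {
    t1 <- periods[i]; t2 <- periods[i + 1]
    ok[i] <- t1 >= floor && t1 <= ceiling && t2 >= floor && t2 <= ceiling &&
      max(t1 / t2, t2 / t1) <= maxfac
  }
  ok
}

oracle_mean_in_range <- function(values, periods, floor = 0.002,
                                 ceiling = 0.025) {
  keep <- periods >= floor & periods <= ceiling
  if (!any(keep)) return(NA_real_)
  mean(values[keep])
}

oracle_consecutive <- function(values, periods, transform = identity,
                               floor = 0.002, ceiling = 0.025, maxfac = 1.3) {
  ok <- oracle_pair_valid(periods, floor, ceiling, maxfac)
  terms <- c()
  for (i in which(ok)) {
    terms <- c(terms, abs(transform(values[i + 1]) - transform(values[i])))
  }
  if (length(terms) == 0) NA_real_ else mean(terms)
}

oracle_window <- function(values, periods, width, floor = 0.002,
                          ceiling = 0.025) {
  n <- length(values)
  half <- (width - 1) / 2
  in_range <- periods >= floor & periods <= ceiling
  terms <- c()
  for (i in seq_len(n)) {
    if (i - half < 1 || i + half > n) next
    w <- (i - half):(i + half)
    if (!all(in_range[w])) next
    terms <- c(terms, abs(values[i] - mean(values[w])))
  }
  if (length(terms) == 0) NA_real_ else mean(terms)
}

oracle_jitter <- function(periods, floor = 0.002, ceiling = 0.025,
                          maxfac = 1.3) {
  mt <- oracle_mean_in_range(periods, periods, floor, ceiling)
  jabs <- oracle_consecutive(periods, periods, identity, floor, ceiling,
                             maxfac)
  list(
    absolute = jabs,
    relative = 100 * jabs / mt,
    rap = 100 * oracle_window(periods, periods, 3, floor, ceiling) / mt,
    ppq5 = 100 * oracle_window(periods, periods, 5, floor, ceiling) / mt
  )
}

oracle_shimmer <- function(periods, amps, floor = 0.002, ceiling = 0.025,
                           maxfac = 1.3) {
  ma <- oracle_mean_in_range(amps, periods, floor, ceiling)
  list(
    db = oracle_consecutive(amps, periods, function(a) 20 * log10(a),
                            floor, ceiling, maxfac),
    relative = 100 * oracle_consecutive(amps, periods, identity, floor,
                                        ceiling, maxfac) / ma,
    apq3 = 100 * oracle_window(amps, periods, 3, floor, ceiling) / ma,
    apq5 = 100 * oracle_window(amps, periods, 5, floor, ceiling) / ma,
    apq11 = 100 * oracle_window(amps, periods, 11, floor, ceiling) / ma
  )
}

# random cycle sequences spanning defined and undefined regimes
random_cycle_case <- function() {
  n <- sample(2:30, 1)
  periods <- runif(n, 0.004, 0.012) *
    (1 + sample(c(0, 0.5), n, replace = TRUE, prob = c(0.9, 0.1)))
  amps <- runif(n, 0.2, 1.5)
  tibble::tibble(time_s = cumsum(c(0, periods[-n])), period_s = periods,
                 peak_amplitude = amps)
}

expect_same_or_both_na <- function(a, b, tol = 1e-12) {
  if (is.na(a) || is.na(b)) {
    expect_true(is.na(a) && is.na(b))
  } else {
    expect_equal(a, b, tolerance = tol)
  }
}
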