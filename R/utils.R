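# Internal numeric helpers shared by the signal-processing stages.

# Deterministic sub-seed derivation (Lehmer step); stays inside 32-bit range.
derive_seed <- function(seed, ...) {
  extra <- sum(c(...)) %% 2147483647
  as.integer((as.numeric(seed %% 2147483647) * 48271 + extra) %% 2147483647)
}

hann_window <- function(n) {
  if (n == 1) return(1)
  0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
}

# Normalized autocorrelation of the Hann window itself, as a function of
# x = lag / window length. Used to undo the taper bias of windowed frame
# autocorrelations so that a perfectly periodic frame scores r ~ 1 at its
# period lag regardless of the period / window-length ratio.
hann_acf <- function(x) {
  x <- pmin(pmax(x, 0), 1)
  (1 - x) * (2 / 3 + (1 / 3) * cos(2 * pi * x)) + sin(2 * pi * x) / (2 * pi)
}

# Biased sample autocorrelation via FFT, normalized by lag 0.
# Returns r[k] for lags 0..(n-1) as a vector indexed from 1 (lag 0).
frame_acf <- function(x) {
  n <- length(x)
  nfft <- 2^ceiling(log2(2 * n))
  X <- fft(c(x, rep(0, nfft - n)))
  r <- Re(fft(Mod(X)^2, inverse = TRUE))[seq_len(n)]
  if (r[1] <= 0) return(rep(0, n))
  r / r[1]
}

# Parabolic (3-point) interpolation around a discrete peak at index i.
# Returns list(offset, value) with offset in samples relative to i.
parabolic_refine <- function(y, i) {
  if (i <= 1 || i >= length(y)) return(list(offset = 0, value = y[i]))
  a <- y[i - 1]; b <- y[i]; c <- y[i + 1]
  denom <- a - 2 * b + c
  if (!is.finite(denom) || abs(denom) < .Machine$double.eps) {
    return(list(offset = 0, value = b))
  }
  off <- 0.5 * (a - c) / denom
  off <- max(min(off, 0.5), -0.5)
  val <- b - 0.25 * (a - c) * off
  list(offset = off, value = val)
}

# Indices of strict local maxima of y within [from, to] (inclusive).
local_maxima <- function(y, from, to) {
  from <- max(from, 2)
  to <- min(to, length(y) - 1)
  if (to < from) return(integer(0))
  idx <- seq(from, to)
  idx[y[idx] > y[idx - 1] & y[idx] >= y[idx + 1]]
}

# Frame picker shared by the pitch tracker and the harmonicity stage:
# lowest-lag strong local maximum of the taper-corrected autocorrelation.
# Peaks at integer multiples of the fundamental period have near-equal
# corrected height for periodic signals; preferring the smallest strong lag
# resolves the octave ambiguity towards the true fundamental.
acf_peak <- function(x, fs, lag_min, lag_max, strong_frac = 0.85) {
  n <- length(x)
  lag_max <- min(lag_max, floor(0.75 * n))
  if (lag_max - lag_min < 2) return(NULL)
  xc <- x - mean(x)
  r <- frame_acf(xc * hann_window(n))
  lags <- seq_len(n) - 1
  corr <- hann_acf(lags / (n - 1))
  rc <- r
  ok <- corr > 0.05
  rc[ok] <- r[ok] / corr[ok]
  rc[!ok] <- 0
  peaks <- local_maxima(rc, lag_min + 1, lag_max + 1)  # +1: index 1 is lag 0
  peaks <- peaks[rc[peaks] > 0]
  if (length(peaks) == 0) return(NULL)
  rmax <- max(rc[peaks])
  strong <- peaks[rc[peaks] >= strong_frac * rmax]
  i <- min(strong)
  ref <- parabolic_refine(rc, i)
  list(lag = (i - 1) + ref$offset, r = ref$value)
}

# Short-time RMS over frames; returns tibble(start, end, rms) in samples.
frame_rms <- function(x, win, hop) {
  n <- length(x)
  if (n < win) {
    return(tibble(start = 1L, end = n, rms = sqrt(mean(x^2))))
  }
  starts <- seq(1L, n - win + 1L, by = hop)
  cs <- c(0, cumsum(x^2))
  rms <- sqrt((cs[starts + win] - cs[starts]) / win)
  tibble(start = starts, end = starts + win - 1L, rms = rms)
}

# Longest run of TRUE; returns c(first, last) indices or NULL.
longest_true_run <- function(flag) {
  if (!any(flag)) return(NULL)
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]
  c(starts[best], ends[best])
}

sample_sd <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) return(NA_real_)
  sd(x)
}
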