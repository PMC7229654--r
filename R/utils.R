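# Small internal helpers shared across modules.

#' Truncated-normal draws by rejection
#'
#' Rejection sampling is exact and fast here because truncation bounds are
#' always several SDs wide.
#' @noRd
rtruncnorm <- function(n, mean, sd, lower, upper) {
  lower <- rep_len(lower, n)
  upper <- rep_len(upper, n)
  if (sd <= 0) return(pmin(pmax(rep_len(mean, n), lower), upper))
  out <- rnorm(n, mean, sd)
  bad <- which(out < lower | out > upper)
  while (length(bad) > 0L) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lower[bad] | out[bad] > upper[bad]]
  }
  out
}

#' 1/f ("pink") noise via spectral shaping
#'
#' White Gaussian noise is Fourier-transformed, its amplitude spectrum scaled
#' by 1/sqrt(f) (flattened below `f_floor` to keep DC/very-low frequencies
#' finite), and transformed back. The result is rescaled to the requested SD.
#' @noRd
one_over_f_noise <- function(n, fs, sd = 1, f_floor = 1) {
  if (n < 2L) return(rnorm(n, 0, sd))
  m <- stats::nextn(n)             # composite length keeps the FFT O(m log m)
  x <- rnorm(m)
  X <- fft(x)
  f <- c(seq_len(ceiling(m / 2) + 1L) - 1L) * fs / m    # 0 .. nyquist-ish
  f <- pmax(f, f_floor)
  scale_half <- 1 / sqrt(f)
  # build full-length symmetric scaling (real signal)
  scl <- numeric(m)
  half <- length(scale_half)
  scl[seq_len(half)] <- scale_half
  if (m > half) scl[(half + 1L):m] <- rev(scale_half[2:(m - half + 1L)])
  y <- Re(fft(X * scl, inverse = TRUE))[seq_len(n)] / m
  s <- stats::sd(y)
  if (s == 0) return(rep(0, n))
  y * (sd / s)
}

#' Hann-shaped (raised-cosine) bump on [t0, t1), zero outside
#' @noRd
raised_cosine <- function(t, t0, t1) {
  out <- numeric(length(t))
  inside <- t >= t0 & t < t1
  out[inside] <- 0.5 * (1 - cos(2 * pi * (t[inside] - t0) / (t1 - t0)))
  out
}

#' Derive a child RNG seed from a master seed (kept below 2^31)
#' @noRd
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(index) * 104729) %% 2147483647)
}

#' Sample index of a time point, 0-based, floor convention
#' @noRd
time_to_sample <- function(t, fs) as.integer(floor(t * fs))

`%||%` <- function(a, b) if (is.null(a)) b else a
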