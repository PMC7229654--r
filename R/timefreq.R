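# Morlet wavelet time-frequency transform and prestimulus alpha extraction.

#' Morlet cycle rule
#'
#' Linear interpolation of the wavelet length in cycles between 4 cycles at
#' 5 Hz and 10 cycles at 40 Hz: cycles(f) = 4 + (f - 5) * 6 / 35. At 10 Hz
#' this gives 4.857 cycles (4.9 to one decimal).
#'
#' @param f frequency, Hz, within [5, 40].
#' @return number of cycles.
#' @export
morlet_cycles <- function(f) {
  if (any(f < 5 | f > 40)) stop("frequency must lie in [5, 40] Hz")
  4 + (f - 5) * 6 / 35
}

#' Spectral FWHM of a Morlet wavelet
#'
#' With time-domain SD sigma_t = cycles / (2 pi f), the spectral SD is
#' f / cycles and the full width at half maximum of the (Gaussian) spectral
#' window is 2 sqrt(2 ln 2) f / cycles -- 4.85 Hz at 10 Hz with 4.857
#' cycles.
#'
#' @param f frequency, Hz.
#' @param cycles wavelet length in cycles (default per [morlet_cycles()]).
#' @return spectral FWHM, Hz.
#' @export
morlet_fwhm <- function(f, cycles = morlet_cycles(f)) {
  2 * sqrt(2 * log(2)) * f / cycles
}

# Complex Morlet wavelet sampled at fs, support +/- 3 sigma_t, normalized so
# a unit-amplitude sinusoid at f yields modulus 1.
morlet_wavelet <- function(f, fs, cycles = morlet_cycles(f)) {
  sigma_t <- cycles / (2 * pi * f)
  half <- ceiling(3 * sigma_t * fs)
  t <- seq(-half, half) / fs
  env <- exp(-t^2 / (2 * sigma_t^2))
  w <- env * exp(1i * 2 * pi * f * t)
  w * (2 / sum(env))
}

#' Morlet time-frequency transform of an epoch set
#'
#' Convolves every trial and channel with complex Morlet wavelets
#' (time-domain SD sigma_t = cycles / (2 pi f)) and returns amplitude
#' (modulus) normalized so a unit sinusoid maps to 1. Edge samples closer to
#' the epoch boundary than half the wavelet support are flagged invalid
#' (returned in `edge_invalid`).
#'
#' @param epochs an `epoch_set`.
#' @param freqs frequencies, Hz (each within [5, 40]).
#' @param channels channel subset; default all.
#' @return list of class `tfr`: `amplitude` (trials x channels x freqs x
#'   time array), `times`, `freqs`, `cycles`, `channels`, `edge_invalid`
#'   (freqs x time logical).
#' @export
morlet_tfr <- function(epochs, freqs, channels = epochs$channels) {
  stopifnot(inherits(epochs, "epoch_set"))
  cyc <- morlet_cycles(freqs)
  n_time <- length(epochs$times)
  wavelets <- lapply(seq_along(freqs), function(k) {
    morlet_wavelet(freqs[k], epochs$fs, cyc[k])
  })
  halves <- vapply(wavelets, function(w) (length(w) - 1L) %/% 2L, integer(1))
  if (any(2L * halves + 1L > n_time)) {
    stop("epoch shorter than the wavelet at the lowest frequency")
  }
  cidx <- match(channels, epochs$channels)
  if (anyNA(cidx)) stop("unknown channel(s) requested")
  n_tr <- dim(epochs$data)[1]
  amp <- array(NA_real_,
               dim = c(n_tr, length(cidx), length(freqs), n_time),
               dimnames = list(NULL, channels, NULL, NULL))
  nfft <- stats::nextn(n_time + max(2L * halves))
  for (k in seq_along(freqs)) {
    wf <- fft(c(wavelets[[k]], numeric(nfft - length(wavelets[[k]]))))
    for (ci in seq_along(cidx)) {
      for (tr in seq_len(n_tr)) {
        x <- epochs$data[tr, cidx[ci], ]
        conv <- fft(fft(c(x, numeric(nfft - n_time))) * wf, inverse = TRUE) / nfft
        amp[tr, ci, k, ] <- Mod(conv[halves[k] + seq_len(n_time)])
      }
    }
  }
  edge <- matrix(FALSE, length(freqs), n_time)
  for (k in seq_along(freqs)) {
    h <- halves[k]
    if (h > 0) edge[k, c(seq_len(min(h, n_time)),
                         seq.int(max(1L, n_time - h + 1L), n_time))] <- TRUE
  }
  structure(list(amplitude = amp, times = epochs$times, freqs = freqs,
                 cycles = cyc, channels = channels, edge_invalid = edge),
            class = "tfr")
}

#' Per-trial prestimulus alpha amplitude
#'
#' Mean Morlet amplitude over the alpha band and the prestimulus window at
#' the sensorimotor channel. The window must be clear of wavelet edge
#' artifacts.
#'
#' @param epochs an `epoch_set` locked to stimulus onset.
#' @param channel sensorimotor channel, default `"C4"`.
#' @param band alpha band, Hz, default 8-13 (evaluated at 1-Hz steps).
#' @param window prestimulus window, s, default `c(-0.3, 0)`.
#' @param tfr optional precomputed [morlet_tfr()] on the band (must include
#'   `channel`); computed on demand when NULL.
#' @return numeric vector of per-trial alpha amplitudes (microvolts).
#' @export
prestim_alpha <- function(epochs, channel = "C4", band = c(8, 13),
                          window = c(-0.3, 0), tfr = NULL) {
  freqs <- seq(band[1], band[2], by = 1)
  if (is.null(tfr)) tfr <- morlet_tfr(epochs, freqs, channels = channel)
  ci <- match(channel, tfr$channels)
  if (is.na(ci)) stop("channel '", channel, "' not in the TFR")
  fidx <- which(tfr$freqs >= band[1] & tfr$freqs <= band[2])
  widx <- which(tfr$times >= window[1] & tfr$times < window[2])
  if (length(widx) == 0L) stop("prestimulus window outside the epoch")
  if (any(tfr$edge_invalid[fidx, widx])) {
    stop("prestimulus window overlaps the wavelet edge-artifact zone")
  }
  apply(tfr$amplitude[, ci, fidx, widx, drop = FALSE], 1, mean)
}
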