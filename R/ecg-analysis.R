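# ECG parsing: R-peak detection, trapezoid t-wave-end estimation,
# equal-length systole/diastole windows, HRV metrics.

#' Detect R-peaks in an ECG trace
#'
#' Amplitude-threshold detector: the trace is centred on its median, local
#' maxima above a fraction of the robust amplitude ceiling (99.5th
#' percentile) are kept, and a refractory period is enforced by retaining
#' only the largest peak within any refractory window.
#'
#' @param record list with `samples` and `fs` (an ECG record), or a numeric
#'   vector (then `fs` must be given).
#' @param fs sampling rate, Hz; taken from `record` when it is a list.
#' @param threshold_frac detection threshold as a fraction of the robust
#'   amplitude ceiling.
#' @param refractory minimum distance between successive peaks, seconds.
#' @return numeric vector of R-peak times, seconds. A flat or empty signal
#'   returns `numeric(0)` with a warning.
#' @export
detect_r_peaks <- function(record, fs = NULL, threshold_frac = 0.5,
                           refractory = 0.25) {
  if (is.list(record)) {
    fs <- record$fs
    x <- record$samples
  } else {
    x <- record
  }
  stopifnot(!is.null(fs), fs > 0)
  if (length(x) < fs * 10) stop("need at least 10 s of ECG signal")
  x <- x - median(x)
  ceiling_amp <- as.numeric(quantile(x, 0.995))
  if (ceiling_amp <= 0 || stats::sd(x) == 0) {
    warning("flat ECG signal: no R-peaks detected")
    return(numeric(0))
  }
  thr <- threshold_frac * ceiling_amp
  n <- length(x)
  is_peak <- c(FALSE, x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n], FALSE) &
    x > thr
  cand <- which(is_peak)
  if (length(cand) == 0L) {
    warning("no suprathreshold peaks in ECG signal")
    return(numeric(0))
  }
  # refractory: greedy scan keeping the larger of two conflicting peaks
  keep <- integer(0)
  ref_samp <- refractory * fs
  for (i in cand) {
    if (length(keep) == 0L || i - keep[length(keep)] >= ref_samp) {
      keep <- c(keep, i)
    } else if (x[i] > x[keep[length(keep)]]) {
      keep[length(keep)] <- i
    }
  }
  (keep - 1L) / fs
}

#' T-wave end by the trapezium-area algorithm
#'
#' Per cardiac cycle, the T-peak is the signal maximum in a search window
#' from R + 150 ms to R + min(500 ms, 0.6 RR). The t-wave end is the point
#' x_m on the descending limb, between the T-peak and a limit point 200 ms
#' after it (clipped to the cycle end), that maximizes the trapezium area
#' A = 0.5 (y_peak - y_m) (2 x_limit - x_m - x_peak).
#'
#' @param record ECG record (list with `samples`, `fs`) or numeric vector.
#' @param r_peaks R-peak times, seconds.
#' @param fs sampling rate if `record` is a bare vector.
#' @param search_min,search_max T-peak search window offsets from R, seconds
#'   (the upper edge is additionally clipped to 0.6 RR).
#' @param limit_offset limit-point offset after the T-peak, seconds.
#' @return data.frame with one row per complete cycle: `r_onset_s`,
#'   `t_end_s` (NA when flagged), `t_peak_s`, `valid`.
#' @export
twave_end_trapezoid <- function(record, r_peaks, fs = NULL,
                                search_min = 0.15, search_max = 0.5,
                                limit_offset = 0.2) {
  if (is.list(record)) {
    fs <- record$fs
    x <- record$samples
  } else {
    x <- record
  }
  stopifnot(!is.null(fs), fs > 0)
  n_cyc <- length(r_peaks) - 1L
  if (n_cyc < 1L) stop("need at least one complete cardiac cycle")
  out <- data.frame(r_onset_s = r_peaks[seq_len(n_cyc)],
                    t_end_s = NA_real_, t_peak_s = NA_real_,
                    valid = FALSE)
  n <- length(x)
  for (k in seq_len(n_cyc)) {
    r0 <- r_peaks[k]
    rr <- r_peaks[k + 1L] - r0
    w_lo <- time_to_sample(r0 + search_min, fs) + 1L
    w_hi <- time_to_sample(r0 + min(search_max, 0.6 * rr), fs) + 1L
    w_hi <- min(w_hi, n)
    if (w_hi <= w_lo) next                        # very short RR: flag invalid
    win <- x[w_lo:w_hi]
    if (max(win) <= 0 || stats::sd(win) == 0) next  # degenerate/absent T wave
    ip <- w_lo + which.max(win) - 1L
    x_peak <- (ip - 1L) / fs
    y_peak <- x[ip]
    lim_t <- min(x_peak + limit_offset, r_peaks[k + 1L] - 1 / fs)
    il <- min(time_to_sample(lim_t, fs) + 1L, n)
    if (il <= ip + 1L) next
    x_lim <- (il - 1L) / fs
    idx <- seq(ip + 1L, il)
    xm <- (idx - 1L) / fs
    ym <- x[idx]
    area <- 0.5 * (y_peak - ym) * (2 * x_lim - xm - x_peak)
    im <- which.max(area)
    if (!is.finite(area[im]) || area[im] <= 0) next
    out$t_end_s[k] <- xm[im]
    out$t_peak_s[k] <- x_peak
    out$valid[k] <- TRUE
  }
  out
}

#' Build the cardiac cycle table
#'
#' Combines R-peaks and t-wave ends into per-cycle systole and diastole
#' windows: systole is the half-open interval [R, t_end); diastole is an
#' equal-length window ending at the next R-peak. Cycles whose systole
#' length deviates more than 4 SDs from the subject mean (single pass), whose
#' windows would overlap (2 x systole > RR), or whose t-wave end failed are
#' flagged invalid -- never dropped.
#'
#' @param r_peaks R-peak times, seconds.
#' @param t_ends t-wave end times, seconds, one per complete cycle (NA for
#'   failed cycles), e.g. `twave_end_trapezoid(...)$t_end_s`.
#' @param sd_limit outlier rule threshold in SD units.
#' @return data.frame of class `cycle_table`: `cycle`, `r_onset_s`,
#'   `r_next_s`, `t_end_s`, `systole_len_s`, `sys_start_s`, `sys_end_s`,
#'   `dia_start_s`, `dia_end_s`, `valid`.
#' @export
build_cycle_table <- function(r_peaks, t_ends, sd_limit = 4) {
  n_cyc <- length(r_peaks) - 1L
  stopifnot(length(t_ends) == n_cyc)
  r0 <- r_peaks[seq_len(n_cyc)]
  r1 <- r_peaks[seq_len(n_cyc) + 1L]
  sys_len <- t_ends - r0
  valid <- !is.na(t_ends) & t_ends > r0 & 2 * sys_len <= (r1 - r0)
  if (sum(valid) < 3L) stop("fewer than 3 valid cycles: systole SD undefined")
  m <- mean(sys_len[valid])
  s <- stats::sd(sys_len[valid])
  if (s > 0) {
    valid <- valid & abs(sys_len - m) <= sd_limit * s
    valid[is.na(valid)] <- FALSE
  }
  out <- data.frame(
    cycle = seq_len(n_cyc),
    r_onset_s = r0, r_next_s = r1, t_end_s = t_ends,
    systole_len_s = sys_len,
    sys_start_s = r0, sys_end_s = t_ends,
    dia_start_s = r1 - sys_len, dia_end_s = r1,
    valid = valid
  )
  class(out) <- c("cycle_table", "data.frame")
  out
}

#' Heart-rate-variability summary
#'
#' SDNN is the SD (n - 1 denominator) of successive RR intervals in
#' milliseconds; `ln_sdnn` its natural log (NA when SDNN is 0); `mean_hr`
#' is 60 / mean RR in beats per minute.
#'
#' @param r_peaks R-peak times, seconds (at least 3).
#' @return list with `mean_hr`, `sdnn`, `ln_sdnn`.
#' @export
hrv_metrics <- function(r_peaks) {
  if (length(r_peaks) < 3L) stop("need at least 3 R-peaks for HRV")
  rr <- diff(r_peaks)
  sdnn <- stats::sd(rr) * 1000
  list(mean_hr = 60 / mean(rr),
       sdnn = sdnn,
       ln_sdnn = if (sdnn > 0) log(sdnn) else NA_real_)
}

#' Write a cycle table as tab-separated values
#'
#' @param cycles a `cycle_table`.
#' @param path output file.
#' @export
write_cycle_table <- function(cycles, path) {
  utils::write.table(as.data.frame(cycles), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
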