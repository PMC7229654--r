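# Filtering, epoching, cardiac-artifact estimation/subtraction, SEP/HEP
# amplitude extraction, amplitude binning.

#' Construct an epoch-set container
#' @noRd
new_epoch_set <- function(data, times, fs, channels, metadata) {
  stopifnot(length(dim(data)) == 3L, dim(data)[2] == length(channels),
            dim(data)[3] == length(times), nrow(metadata) == dim(data)[1])
  structure(list(data = data, times = times, fs = fs,
                 channels = channels, metadata = metadata),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d trials x %d channels x %d samples [%g, %g) s\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              min(x$times), max(x$times) + 1 / x$fs))
  invisible(x)
}

#' Filter, resample and re-reference continuous EEG
#'
#' Antialiasing low-pass at 0.45 fs_out followed by decimation to `fs_out`
#' (integer factors decimate directly; non-integer ratios fall back to
#' polyphase resampling with a log message), then a zero-phase 4th-order
#' Butterworth band limit applied as two passes (high-pass 0.5 Hz, then
#' low-pass 45 Hz), then average reference across EEG channels (the ECG
#' channel is band-limited but excluded from, and not re-referenced to, the
#' average).
#'
#' @param data channels x samples matrix (rownames = channel names).
#' @param fs_in input sampling rate, Hz.
#' @param fs_out target rate, Hz.
#' @param eeg_channels channel names entering the average reference; defaults
#'   to all rows except `"ECG"`.
#' @param hp,lp band edges, Hz.
#' @param average_ref logical; apply the average reference.
#' @return list with `data` (filtered matrix) and `fs` (= fs_out).
#' @export
preprocess <- function(data, fs_in, fs_out = 250, eeg_channels = NULL,
                       hp = 0.5, lp = 45, average_ref = TRUE) {
  stopifnot(is.matrix(data), fs_in >= fs_out)
  channels <- rownames(data)
  if (is.null(eeg_channels)) eeg_channels <- setdiff(channels, "ECG")
  if (fs_in > fs_out) {
    aa <- signal::butter(4, (0.45 * fs_out) / (fs_in / 2), type = "low")
    data <- t(apply(data, 1, function(x) signal::filtfilt(aa, x)))
    fac <- fs_in / fs_out
    if (abs(fac - round(fac)) < 1e-9) {
      data <- data[, seq(1, ncol(data), by = round(fac)), drop = FALSE]
    } else {
      message("non-integer decimation factor ", signif(fac, 4),
              ": polyphase resampling")
      data <- t(apply(data, 1, function(x) signal::resample(x, fs_out, fs_in)))
    }
  }
  bh <- signal::butter(4, hp / (fs_out / 2), type = "high")
  bl <- signal::butter(4, lp / (fs_out / 2), type = "low")
  data <- t(apply(data, 1, function(x) {
    signal::filtfilt(bl, signal::filtfilt(bh, x))
  }))
  rownames(data) <- channels
  if (average_ref && length(eeg_channels) > 1L) {
    ref <- colMeans(data[eeg_channels, , drop = FALSE])
    data[eeg_channels, ] <- sweep(data[eeg_channels, , drop = FALSE], 2, ref)
  }
  list(data = data, fs = fs_out)
}

#' Segment continuous data into baseline-corrected epochs
#'
#' Epochs are half-open windows `[window[1], window[2])` around each event;
#' the per-channel mean of the baseline window is subtracted per trial.
#' Events whose window is not fully covered by the recording are dropped with
#' a message.
#'
#' @param data channels x samples matrix with channel rownames.
#' @param fs sampling rate, Hz.
#' @param events event times, seconds.
#' @param window epoch window (s relative to event), default `c(-1, 2)`.
#' @param baseline baseline window, default `c(-0.1, 0)`; NULL skips
#'   baseline correction.
#' @param metadata optional data.frame (one row per event) carried along;
#'   rows of dropped events are removed.
#' @return an `epoch_set`.
#' @export
epoch_data <- function(data, fs, events, window = c(-1, 2),
                       baseline = c(-0.1, 0), metadata = NULL) {
  stopifnot(is.matrix(data))
  channels <- rownames(data)
  offs <- seq.int(round(window[1] * fs), round(window[2] * fs) - 1L)
  times <- offs / fs
  n_samp <- ncol(data)
  anchor <- time_to_sample(events, fs) + 1L
  ok <- (anchor + offs[1]) >= 1L & (anchor + offs[length(offs)]) <= n_samp
  if (!any(ok)) stop("no event has full epoch coverage")
  if (any(!ok)) message(sum(!ok), " event(s) without full window coverage dropped")
  events <- events[ok]
  anchor <- anchor[ok]
  if (is.null(metadata)) metadata <- data.frame(event_s = events)
  else {
    metadata <- metadata[ok, , drop = FALSE]
    metadata$event_s <- events
  }
  n_tr <- length(events)
  arr <- array(NA_real_, dim = c(n_tr, length(channels), length(times)))
  for (i in seq_len(n_tr)) {
    arr[i, , ] <- data[, anchor[i] + offs, drop = FALSE]
  }
  if (!is.null(baseline)) {
    bidx <- which(times >= baseline[1] & times < baseline[2])
    if (length(bidx) == 0L) stop("baseline window contains no samples")
    bmean <- apply(arr[, , bidx, drop = FALSE], c(1, 2), mean)
    arr <- arr - array(bmean, dim = dim(arr))   # recycled over time (3rd dim last)
  }
  new_epoch_set(arr, times, fs, channels, metadata)
}

#' Estimate the cardiac field artifact from random triggers
#'
#' Places random triggers uniformly inside stimulation-free cardiac cycles,
#' classifies each trigger as systole or diastole from the cycle windows,
#' epochs the data around the triggers (baseline-corrected 100-0 ms before
#' trigger onset) and averages per phase, yielding one artifact template per
#' phase for every channel.
#'
#' @param data channels x samples matrix.
#' @param fs sampling rate, Hz.
#' @param cycles a [build_cycle_table()] result.
#' @param stim_onsets stimulus onset times, s; cycles within `pad` seconds of
#'   any onset are excluded from trigger placement.
#' @param n_triggers number of random triggers to draw.
#' @param pad guard interval around stimulus onsets, seconds.
#' @param window,baseline epoching parameters (s relative to trigger).
#' @param seed optional RNG seed for reproducible trigger placement.
#' @return list of class `artifact_template` with elements `systole` and
#'   `diastole` (channels x time matrices), `times`, `n_triggers` (per
#'   phase), `channels`.
#' @export
estimate_cardiac_artifact <- function(data, fs, cycles, stim_onsets,
                                      n_triggers = 400, pad = 0.7,
                                      window = c(-1, 2), baseline = c(-0.1, 0),
                                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  free <- cycles$valid
  if (length(stim_onsets) > 0) {
    for (k in which(free)) {
      if (any(stim_onsets > cycles$r_onset_s[k] - pad &
              stim_onsets < cycles$r_next_s[k] + pad)) free[k] <- FALSE
    }
  }
  free_idx <- which(free)
  if (length(free_idx) < 100L) {
    stop("need at least 100 stimulation-free cardiac cycles, found ",
         length(free_idx))
  }
  durs <- cycles$r_next_s[free_idx] - cycles$r_onset_s[free_idx]
  pick <- sample(free_idx, n_triggers, replace = TRUE, prob = durs)
  trig <- cycles$r_onset_s[pick] +
    runif(n_triggers) * (cycles$r_next_s[pick] - cycles$r_onset_s[pick])
  phase <- classify_phase(trig, cycles)
  keep <- phase %in% c("systole", "diastole")
  ep <- epoch_data(data, fs, trig[keep], window = window, baseline = baseline,
                   metadata = data.frame(phase = phase[keep]))
  out <- list(times = ep$times, channels = ep$channels,
              n_triggers = c(systole = 0, diastole = 0))
  for (ph in c("systole", "diastole")) {
    sel <- which(ep$metadata$phase == ph)
    out$n_triggers[ph] <- length(sel)
    if (length(sel) < 50L) {
      warning("only ", length(sel), " ", ph, " triggers for artifact template")
    }
    if (length(sel) == 0L) {
      out[[ph]] <- matrix(0, length(ep$channels), length(ep$times))
    } else {
      out[[ph]] <- apply(ep$data[sel, , , drop = FALSE], c(2, 3), mean)
    }
    dimnames(out[[ph]]) <- list(ep$channels, NULL)
  }
  class(out) <- "artifact_template"
  out
}

#' Subtract phase-matched cardiac artifact templates from epochs
#'
#' Each trial's template (by its `phase` metadata label) is subtracted
#' sample-wise. Trials labelled `neither`/`invalid_cycle` are left
#' uncorrected and flagged in `metadata$artifact_corrected`.
#'
#' @param epochs an `epoch_set` whose metadata has a `phase` column.
#' @param templates an `artifact_template` from
#'   [estimate_cardiac_artifact()]; its time axis must cover the epoch axis.
#' @return the corrected `epoch_set`.
#' @export
correct_epochs <- function(epochs, templates) {
  stopifnot(inherits(epochs, "epoch_set"), inherits(templates, "artifact_template"))
  tidx <- match(round(epochs$times * epochs$fs), round(templates$times * epochs$fs))
  if (anyNA(tidx)) stop("template time axis does not cover the epoch axis")
  cidx <- match(epochs$channels, templates$channels)
  if (anyNA(cidx)) stop("template channels do not cover the epoch channels")
  corrected <- logical(nrow(epochs$metadata))
  for (i in seq_len(dim(epochs$data)[1])) {
    ph <- epochs$metadata$phase[i]
    if (!ph %in% c("systole", "diastole")) next
    epochs$data[i, , ] <- epochs$data[i, , ] - templates[[ph]][cidx, tidx]
    corrected[i] <- TRUE
  }
  epochs$metadata$artifact_corrected <- corrected
  epochs
}

#' Mean component amplitude in a time window
#'
#' Mean microvolt amplitude over a half-open time window at one channel, per
#' trial, and optionally averaged within levels of a metadata column.
#'
#' @param epochs an `epoch_set`.
#' @param channel channel name (default `"C4"`, the contralateral
#'   somatosensory electrode).
#' @param window half-open window in seconds, e.g. `c(0.268, 0.468)`.
#' @param by optional metadata column name for condition means.
#' @return list with `per_trial` (numeric vector) and, when `by` is given,
#'   `condition_means` (data.frame `condition`, `mean`, `n`).
#' @export
component_amplitude <- function(epochs, channel = "C4", window, by = NULL) {
  ci <- match(channel, epochs$channels)
  if (is.na(ci)) {
    stop("unknown channel '", channel, "'; available: ",
         paste(epochs$channels, collapse = ", "))
  }
  widx <- which(epochs$times >= window[1] & epochs$times < window[2])
  if (length(widx) == 0L) stop("window lies outside the epoch")
  per_trial <- apply(epochs$data[, ci, widx, drop = FALSE], 1, mean)
  out <- list(per_trial = per_trial)
  if (!is.null(by)) {
    f <- factor(epochs$metadata[[by]])
    means <- tapply(per_trial, f, mean)
    out$condition_means <- data.frame(condition = names(means),
                                      mean = as.numeric(means),
                                      n = as.integer(table(f)))
  }
  out
}

#' R-peak-locked epochs for HEP analysis
#'
#' For every trial whose stimulus onset is at least `min_delay` (400 ms)
#' after the preceding R-peak, one epoch is extracted locked to that R-peak
#' (so the 250-400 ms HEP window precedes the stimulus). Trials with a
#' shorter delay are excluded. Additionally, R-peak-locked epochs from
#' stimulation-free cycles are returned for the resting-HEP comparison.
#'
#' @param data channels x samples matrix.
#' @param fs sampling rate, Hz.
#' @param r_peaks detected R-peak times, seconds.
#' @param trials classified + phase-annotated trial table.
#' @param cycles a [build_cycle_table()] result (for the stimulation-free
#'   mask).
#' @param min_delay minimum stimulus delay after the preceding R-peak, s.
#' @param pad guard interval defining stimulation-free cycles, s.
#' @param window,baseline epoching parameters relative to the R-peak, s.
#' @param max_rest maximum number of resting epochs (subsampled evenly).
#' @return list with `stim` (epoch_set, metadata = qualifying trial rows)
#'   and `rest` (epoch_set of stimulation-free beats).
#' @export
hep_epochs <- function(data, fs, r_peaks, trials, cycles, min_delay = 0.4,
                       pad = 0.7, window = c(-1, 2), baseline = c(-0.1, 0),
                       max_rest = 400) {
  idx <- findInterval(trials$onset_s, r_peaks)
  covered <- idx >= 1L & idx < length(r_peaks)
  delay <- rep(NA_real_, nrow(trials))
  delay[covered] <- trials$onset_s[covered] - r_peaks[idx[covered]]
  qual <- covered & delay >= min_delay
  if (!any(qual)) stop("no trial satisfies the ", min_delay * 1000,
                       " ms delay rule")
  md <- trials[qual, , drop = FALSE]
  md$r_lock_s <- r_peaks[idx[qual]]
  md$delay_from_r <- delay[qual]
  stim_ep <- epoch_data(data, fs, md$r_lock_s, window = window,
                        baseline = baseline, metadata = md)
  # stimulation-free beats
  free <- cycles$valid
  for (k in which(free)) {
    if (any(trials$onset_s > cycles$r_onset_s[k] - pad &
            trials$onset_s < cycles$r_next_s[k] + pad)) free[k] <- FALSE
  }
  rest_r <- cycles$r_onset_s[free]
  if (length(rest_r) > max_rest) {
    rest_r <- rest_r[round(seq(1, length(rest_r), length.out = max_rest))]
  }
  rest_ep <- NULL
  if (length(rest_r) > 0) {
    rest_ep <- epoch_data(data, fs, rest_r, window = window,
                          baseline = baseline,
                          metadata = data.frame(r_lock_s = rest_r))
  }
  list(stim = stim_ep, rest = rest_ep)
}

#' Equal-count amplitude bins
#'
#' Trials are sorted ascending by value (stable: original order breaks ties)
#' and split into `n_bins` contiguous groups whose sizes differ by at most
#' one, larger bins first.
#'
#' @param values per-trial scalar (e.g. HEP or alpha amplitude).
#' @param n_bins number of bins.
#' @return integer vector of bin labels (1 = lowest amplitudes), aligned
#'   with the input order.
#' @export
amplitude_bins <- function(values, n_bins) {
  n <- length(values)
  stopifnot(n >= n_bins, n_bins >= 1)
  ord <- order(values)                       # radix sort: stable
  base <- n %/% n_bins
  sizes <- base + as.integer(seq_len(n_bins) <= n %% n_bins)
  lab_sorted <- rep(seq_len(n_bins), times = sizes)
  out <- integer(n)
  out[ord] <- lab_sorted
  out
}
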