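# Synthetic cohort generator: coupled ECG + EEG + behaviour with recorded
# ground truth. The generative model mirrors the statistical structure the
# analysis assumes -- phase-dependent sensitivity, HEP/alpha-dependent
# criterion, cardiac field artifact, SEP/HEP/alpha signal injections.

# ---- ECG morphology ---------------------------------------------------------

# Gaussian PQRST component table. Latencies of P/Q/S are fractions of the RR
# interval (P) or fixed offsets near R (Q/S); the T wave is placed so that its
# offset, defined as T-peak + 2.5 sigma_T, equals the recorded true t-wave
# end (R-peak + systole length).
.ecg_t_sigma <- 0.04

#' Render an ECG trace from RR and systole-length series
#'
#' Builds a PQRST Gaussian-mixture train: each cycle contains one dominant R
#' spike (amplitude 1) and one T wave (amplitude 0.25) whose offset -- the
#' ground-truth t-wave end -- is T-peak time + 2.5 T-wave SDs and equals
#' R-peak time + systole length.
#'
#' @param rr_intervals per-cycle RR intervals, seconds.
#' @param systole_lengths per-cycle systole lengths, seconds (same length).
#' @param fs sampling rate, Hz (>= 250).
#' @param lead_in silent head/tail padding before the first R, seconds.
#' @return list with `samples`, `fs`, `r_peaks` (true R times, s) and
#'   `t_ends` (true t-wave ends, s).
#' @export
ecg_waveform <- function(rr_intervals, systole_lengths, fs, lead_in = 0.4) {
  stopifnot(length(rr_intervals) == length(systole_lengths))
  if (fs < 250) stop("fs must be at least 250 Hz")
  n_cyc <- length(rr_intervals)
  if (n_cyc == 0L) {
    return(list(samples = numeric(0), fs = fs,
                r_peaks = numeric(0), t_ends = numeric(0)))
  }
  if (any(systole_lengths >= rr_intervals)) {
    stop("systole length must be shorter than the RR interval")
  }
  r <- lead_in + c(0, cumsum(rr_intervals))[seq_len(n_cyc)]
  duration <- lead_in + sum(rr_intervals) + lead_in
  n_samp <- as.integer(ceiling(duration * fs))
  t_ends <- r + systole_lengths
  samples <- render_pqrst_train(n_samp, fs, r, rr_intervals, systole_lengths)
  list(samples = samples, fs = fs, r_peaks = r, t_ends = t_ends)
}

# Render the Gaussian PQRST train for all beats in one pass.
render_pqrst_train <- function(n_samp, fs, r_peaks, rr, systole) {
  samples <- numeric(n_samp)
  rr <- rep_len(rr, length(r_peaks))
  systole <- rep_len(systole, length(r_peaks))
  add_comp <- function(center, amp, sigma) {
    lo <- max(1L, time_to_sample(center - 4 * sigma, fs) + 1L)
    hi <- min(n_samp, time_to_sample(center + 4 * sigma, fs) + 1L)
    if (lo > hi) return(invisible())
    tt <- (seq(lo, hi) - 1L) / fs
    samples[lo:hi] <<- samples[lo:hi] + amp * exp(-0.5 * ((tt - center) / sigma)^2)
    invisible()
  }
  for (k in seq_along(r_peaks)) {
    rk <- r_peaks[k]
    add_comp(rk + rr[k] - 0.18 * rr[k], 0.10, 0.025)   # P of next beat
    add_comp(rk - 0.025, -0.08, 0.010)                 # Q
    add_comp(rk, 1.00, 0.012)                          # R
    add_comp(rk + 0.030, -0.12, 0.012)                 # S
    add_comp(rk + systole[k] - 2.5 * .ecg_t_sigma, 0.25, .ecg_t_sigma)  # T
  }
  samples
}

# ---- channel gain tables ----------------------------------------------------
# Spatial profiles of injected components, keyed by channel name. Channels not
# listed get zero signal gain (noise only). Values are unitless multipliers of
# the component amplitudes in the config.

.sep_gains <- c(C4 = 1, CP4 = 0.8, Cz = 0.6, P4 = 0.5, Pz = 0.4, F4 = 0.4,
                Fz = 0.3, CP3 = 0.3, C3 = 0.2, O2 = 0.1)
.hep_gains <- c(C4 = 1, CP4 = 1, Cz = 0.8, CP3 = 0.6, C3 = 0.5, Pz = 0.5,
                P4 = 0.4, F4 = 0.3, Fz = 0.2, O2 = 0)
.alpha_gains <- c(C4 = 1, CP4 = 0.9, C3 = 0.9, CP3 = 0.8, Cz = 0.5, Pz = 0.4,
                  P4 = 0.4, O2 = 0.3, F4 = 0.1, Fz = 0.1)
.cfa_gains <- c(Fz = 1, F4 = 0.8, Cz = 0.6, C3 = 0.5, C4 = 0.5, CP3 = 0.45,
                CP4 = 0.45, Pz = 0.4, P4 = 0.35, O2 = 0.25)

gain_for <- function(table, channels) {
  g <- table[channels]
  g[is.na(g)] <- 0
  unname(g)
}

# ---- subject-level generation -----------------------------------------------

#' Generate one synthetic subject
#'
#' Draws the cardiac series (i.i.d. truncated-normal RR intervals, per-cycle
#' systole lengths), schedules stimulation and catch trials in jittered slots
#' so that onsets are uniform over the cardiac cycle, simulates yes/no
#' detection under the equal-variance SDT model with phase-dependent d' and a
#' criterion shifted by per-beat HEP and per-trial alpha latents, and (in
#' `"full"` signal mode) renders the ECG trace and a multichannel EEG
#' containing 1/f noise, sensorimotor alpha with per-trial prestimulus
#' envelope, a cardiac field artifact locked to every R-peak, HEP deflections
#' 250-400 ms after each R-peak, and SEP components (P50, N140, P300) at
#' stimulus onsets.
#'
#' @param config a [cohort_config()].
#' @param subject_seed integer seed for this subject.
#' @return An object of class `subject_dataset`: list with `ecg`, `eeg`
#'   (NULL in behaviour-only mode), `trials` (trial table), `truth` (ground
#'   truth), `config`, `subject_seed`.
#' @export
generate_subject <- function(config, subject_seed = config$seed) {
  validate_config(config)
  set.seed(as.integer(subject_seed))

  n_stim <- config$n_blocks * config$stim_trials_per_block
  n_catch <- config$n_blocks * config$catch_trials_per_block
  n_trials <- n_stim + n_catch
  per_block <- config$stim_trials_per_block + config$catch_trials_per_block
  stim_span <- n_trials * config$mean_iti
  duration <- 0.9 + stim_span + config$rest_duration + 1.0

  # cardiac timing
  n_draw <- as.integer(ceiling(duration / (0.5 * config$mean_rr))) + 4L
  rr_all <- rtruncnorm(n_draw, config$mean_rr, config$sdnn,
                       0.5 * config$mean_rr, 1.5 * config$mean_rr)
  r_all <- 0.4 + c(0, cumsum(rr_all))
  r <- r_all[r_all <= duration - 0.05]
  n_beats <- length(r)
  n_cyc <- n_beats - 1L
  rr <- diff(r)
  systole <- rtruncnorm(n_cyc, config$systole_mean, config$systole_sd,
                        0.12, pmin(0.49 * rr, 0.49 * config$mean_rr))
  t_end_true <- r[seq_len(n_cyc)] + systole
  h_beat <- rnorm(n_beats)

  # trial schedule: jittered slots, catch trials randomized within block
  onset <- 0.9 + (seq_len(n_trials) - 1L) * config$mean_iti +
    runif(n_trials, 0.15, 0.85) * config$mean_iti
  block <- rep(seq_len(config$n_blocks), each = per_block)
  stim <- logical(n_trials)
  finger <- rep(NA_character_, n_trials)
  for (b in seq_len(config$n_blocks)) {
    idx <- which(block == b)
    stim_idx <- sample(idx, config$stim_trials_per_block)
    stim[stim_idx] <- TRUE
    finger[stim_idx] <- sample(rep(c("index", "middle"),
                                   length.out = config$stim_trials_per_block))
  }

  # trial-level latent state
  cyc <- findInterval(onset, r)            # cycle index of preceding R
  stopifnot(all(cyc >= 1L & cyc <= n_cyc))
  delay <- onset - r[cyc]
  rr_i <- rr[cyc]
  sys_i <- systole[cyc]
  phase_true <- ifelse(delay < sys_i, "systole",
                       ifelse(delay >= rr_i - sys_i, "diastole", "neither"))
  d_off <- rnorm(1, 0, config$subject_jitter_dprime)
  c_off <- rnorm(1, 0, config$subject_jitter_criterion)
  if (config$phase_mode == "binary") {
    dprime_i <- ifelse(phase_true == "systole", config$dprime_systole,
                       ifelse(phase_true == "diastole", config$dprime_diastole,
                              (config$dprime_systole + config$dprime_diastole) / 2))
  } else {
    half <- config$smooth_dip_width / 2
    dip <- ifelse(abs(delay - 0.3) < half,
                  config$smooth_dip_amp * cos(pi * (delay - 0.3) / config$smooth_dip_width)^2,
                  0)
    dprime_i <- config$dprime_diastole - dip
  }
  dprime_i <- pmax(dprime_i + d_off, 0)
  h_i <- h_beat[cyc]
  a_i <- rnorm(n_trials)
  crit_i <- config$criterion_base + c_off +
    config$beta_hep * h_i + config$beta_alpha * a_i

  x <- rnorm(n_trials, ifelse(stim, dprime_i / 2, -dprime_i / 2), 1)
  yes <- x > crit_i
  loc_ok <- rep(NA, n_trials)
  response_loc <- rep(NA_character_, n_trials)
  sidx <- which(stim)
  p_loc <- ifelse(yes[sidx], config$loc_correct_hit, config$loc_correct_miss)
  loc_ok[sidx] <- runif(length(sidx)) < p_loc
  other <- ifelse(finger[sidx] == "index", "middle", "index")
  response_loc[sidx] <- ifelse(loc_ok[sidx], finger[sidx], other)
  response_loc[!stim] <- sample(c("index", "middle"), n_catch, replace = TRUE)

  trials <- data.frame(
    trial = seq_len(n_trials), block = block, onset_s = onset,
    stim = stim, finger = finger,
    response_yes = yes, response_loc = response_loc,
    stringsAsFactors = FALSE
  )

  sep_scale <- pmax(0, 1 - config$sep_hep_slope * h_i)
  p300_amp <- config$sep_p300_amp * sep_scale *
    ifelse(stim & yes, config$sep_p300_gain_hit, 1) *
    ifelse(phase_true == "diastole", config$sep_p300_gain_diastole, 1)

  truth <- list(
    r_peaks = r, rr = rr, systole = systole, t_end = t_end_true,
    h_beat = h_beat,
    trial = data.frame(
      trial = seq_len(n_trials), delay_s = delay, rr_s = rr_i,
      phase = phase_true, dprime = dprime_i, criterion = crit_i,
      h = h_i, a = a_i, sep_scale = sep_scale, p300_amp = p300_amp,
      stringsAsFactors = FALSE
    ),
    subject_offsets = c(dprime = d_off, criterion = c_off),
    config = config
  )

  ecg <- NULL
  eeg <- NULL
  if (config$signals == "full") {
    n_samp <- as.integer(ceiling(duration * config$fs))
    # last beat recycles the mean cycle morphology (it has no complete cycle)
    ecg_clean <- render_pqrst_train(n_samp, config$fs, r,
                                    c(rr, mean(rr)), c(systole, mean(systole)))
    ecg_samples <- ecg_clean + rnorm(n_samp, 0, config$ecg_noise_sd)
    ecg <- list(samples = ecg_samples, fs = config$fs)
    eeg <- synthesize_eeg(config, n_samp, ecg_clean, ecg_samples, r, trials, truth)
  }

  out <- list(ecg = ecg, eeg = eeg, trials = trials, truth = truth,
              config = config, subject_seed = as.integer(subject_seed))
  class(out) <- "subject_dataset"
  out
}

# Render the EEG matrix (channels x samples, microvolts).
synthesize_eeg <- function(config, n_samp, ecg_clean, ecg_samples, r, trials, truth) {
  fs <- config$fs
  montage <- config$montage
  eeg_ch <- montage$channel[montage$type == "eeg"]
  channels <- montage$channel
  data <- matrix(0, nrow = length(channels), ncol = n_samp,
                 dimnames = list(channels, NULL))
  tt <- (seq_len(n_samp) - 1L) / fs

  # per-trial prestimulus alpha envelope, shared across channels
  env <- rep(1, n_samp)
  for (i in seq_len(nrow(trials))) {
    lo <- time_to_sample(trials$onset_s[i] - 0.45, fs) + 1L
    hi <- time_to_sample(trials$onset_s[i] + 0.05, fs)
    if (lo < 1L || hi > n_samp || hi <= lo) next
    seg <- seq(lo, hi)
    taper <- 0.5 * (1 - cos(2 * pi * seq(0, 1, length.out = length(seg))))
    env[seg] <- env[seg] + config$alpha_mod * truth$trial$a[i] * taper
  }
  env <- pmax(env, 0)

  a_g <- gain_for(.alpha_gains, channels)
  s_g <- gain_for(.sep_gains, channels)
  h_g <- gain_for(.hep_gains, channels)
  c_g <- gain_for(.cfa_gains, channels)

  hep_amp <- config$hep_base + config$hep_scale * truth$h_beat
  hep_len <- time_to_sample(0.15, fs)   # samples spanning 250-400 ms post R
  hep_shape <- 0.5 * (1 - cos(2 * pi * seq(0, 1, length.out = hep_len)))

  for (ci in seq_along(channels)) {
    ch <- channels[ci]
    if (montage$type[ci] == "ecg") {
      data[ci, ] <- ecg_samples * 500    # ECG electrode, ~500 uV R-peak
      next
    }
    row <- one_over_f_noise(n_samp, fs, sd = config$noise_sd)
    if (a_g[ci] > 0) {
      row <- row + config$alpha_base * a_g[ci] * env *
        sin(2 * pi * 10 * tt + 2 * pi * ci / length(channels))
    }
    row <- row + config$cfa_amp * c_g[ci] * ecg_clean
    if (h_g[ci] > 0) {
      for (b in seq_along(r)) {
        lo <- time_to_sample(r[b] + 0.25, fs) + 1L
        hi <- lo + hep_len - 1L
        if (lo < 1L || hi > n_samp) next
        row[lo:hi] <- row[lo:hi] + h_g[ci] * hep_amp[b] * hep_shape
      }
    }
    if (s_g[ci] > 0) {
      stim_idx <- which(trials$stim)
      for (i in stim_idx) {
        on <- trials$onset_s[i]
        sc <- truth$trial$sep_scale[i]
        lo <- time_to_sample(on, fs) + 1L
        hi <- min(n_samp, time_to_sample(on + 0.5, fs) + 1L)
        if (lo < 1L || hi <= lo) next
        loc_t <- (seq(lo, hi) - 1L) / fs - on
        comp <- config$sep_p50_amp * sc * exp(-0.5 * ((loc_t - 0.05) / 0.008)^2) +
          config$sep_n140_amp * sc * exp(-0.5 * ((loc_t - 0.14) / 0.02)^2) +
          truth$trial$p300_amp[i] * raised_cosine(loc_t, 0.268, 0.468)
        row[lo:hi] <- row[lo:hi] + s_g[ci] * comp
      }
    }
    data[ci, ] <- row
  }
  list(data = data, fs = fs, channels = channels, montage = montage)
}

#' Generate a synthetic cohort
#'
#' Produces `config$n_subjects` subject datasets with subject seeds derived
#' deterministically from the master seed, plus a cohort-level ground-truth
#' summary.
#'
#' @param config a [cohort_config()].
#' @return list with `subjects` (list of `subject_dataset`), `config`,
#'   `subject_seeds`, and `truth_summary` (per-subject generative parameters).
#' @export
generate_cohort <- function(config) {
  validate_config(config)
  seeds <- vapply(seq_len(config$n_subjects),
                  function(i) derive_seed(config$seed, i), integer(1))
  subjects <- lapply(seq_len(config$n_subjects), function(i) {
    generate_subject(config, seeds[i])
  })
  truth_summary <- do.call(rbind, lapply(seq_along(subjects), function(i) {
    tr <- subjects[[i]]$truth
    data.frame(
      subject = i, seed = seeds[i],
      dprime_offset = tr$subject_offsets[["dprime"]],
      criterion_offset = tr$subject_offsets[["criterion"]],
      mean_rr = mean(tr$rr), mean_systole = mean(tr$systole),
      n_trials = nrow(subjects[[i]]$trials)
    )
  }))
  structure(list(subjects = subjects, config = config,
                 subject_seeds = seeds, truth_summary = truth_summary),
            class = "cohort")
}

#' @export
print.subject_dataset <- function(x, ...) {
  cat("<subject_dataset>", nrow(x$trials), "trials,",
      length(x$truth$r_peaks), "heartbeats,",
      if (is.null(x$eeg)) "behaviour-only\n" else
        paste0(nrow(x$eeg$data), " channels at ", x$eeg$fs, " Hz\n"))
  invisible(x)
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort>", length(x$subjects), "subjects, seed", x$config$seed, "\n")
  invisible(x)
}
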