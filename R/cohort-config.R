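#' Default electrode montage
#'
#' Eleven channels: ten EEG electrodes spanning frontal to occipital sites
#' (with the contralateral somatosensory cortex represented by C4 for
#' left-hand stimulation) plus the ECG electrode. Positions are schematic 2D
#' coordinates (head seen from above, nose up) used only for neighbourhood
#' construction and debug topographies, not for source modelling.
#'
#' @return A data.frame with columns `channel`, `x`, `y`, `type`
#'   (`"eeg"`/`"ecg"`).
#' @export
default_montage <- function() {
  data.frame(
    channel = c("Fz", "F4", "Cz", "C3", "C4", "CP3", "CP4", "Pz", "P4", "O2", "ECG"),
    x = c(0, 0.35, 0, -0.35, 0.35, -0.30, 0.30, 0, 0.30, 0.20, 0),
    y = c(0.70, 0.62, 0.35, 0.35, 0.35, 0.12, 0.12, -0.10, -0.14, -0.42, -1.50),
    type = c(rep("eeg", 10L), "ecg"),
    stringsAsFactors = FALSE
  )
}

#' Cohort configuration for the synthetic-data generator
#'
#' Bundles every tunable of the generative model with defaults matching the
#' study design the analysis assumes: 8 blocks of 100 stimulation + 20 catch
#' trials per subject (800/160 in total), systole length 333 +/- 21 ms,
#' phase-dependent sensitivity (d' 1.48 in systole, 1.59 in diastole), a
#' baseline criterion of 0.76 shifted by heartbeat-evoked-potential (HEP) and
#' prestimulus alpha latents, and localization accuracy of 88.9% for hits and
#' 57% for misses.
#'
#' @param n_subjects number of subjects in the cohort.
#' @param fs sampling rate in Hz for ECG and EEG.
#' @param n_blocks,stim_trials_per_block,catch_trials_per_block trial ledger.
#' @param mean_rr,sdnn mean and SD of the RR-interval series, seconds.
#' @param systole_mean,systole_sd per-cycle systole length distribution, s.
#' @param dprime_systole,dprime_diastole detection sensitivity by true phase.
#' @param criterion_base baseline decision criterion c.
#' @param beta_hep,beta_alpha criterion shift (criterion units) per SD of the
#'   HEP and prestimulus-alpha latents.
#' @param loc_correct_hit,loc_correct_miss probability of correct
#'   localization given a hit / a miss.
#' @param sep_p300_gain_hit,sep_p300_gain_diastole multiplicative P300 gains
#'   for detected stimuli and for diastole trials.
#' @param sep_hep_slope fractional attenuation of all SEP components per SD
#'   of the HEP latent (higher HEP, smaller SEPs).
#' @param phase_mode `"binary"` assigns d' by systole/diastole window;
#'   `"smooth"` uses a raised-cosine sensitivity dip centred 300 ms post-R.
#' @param smooth_dip_amp,smooth_dip_width depth (d' units) and full width (s)
#'   of the smooth-mode dip.
#' @param mean_iti mean trial spacing in seconds (onsets are drawn inside
#'   jittered slots so cardiac phase is uniform).
#' @param rest_duration trailing stimulation-free recording segment, s,
#'   providing resting heartbeats for artifact estimation and resting HEPs.
#'   Keep this long enough that artifact triggers are dominated by rest
#'   cycles: cycles squeezed between trials are biased toward short RR
#'   intervals, which skews the artifact template.
#' @param signals `"full"` generates ECG + EEG traces; `"behavior"` generates
#'   only cardiac timing, latents and responses (fast statistical
#'   calibration).
#' @param noise_sd EEG 1/f noise SD, microvolts.
#' @param alpha_base,alpha_mod sensorimotor alpha amplitude (uV) and its
#'   fractional per-trial modulation per SD of the alpha latent.
#' @param hep_base,hep_scale HEP deflection amplitude (uV) and its slope per
#'   SD of the per-beat HEP latent.
#' @param sep_p50_amp,sep_n140_amp,sep_p300_amp SEP component amplitudes, uV.
#' @param cfa_amp cardiac-field-artifact amplitude at the strongest EEG
#'   channel, uV.
#' @param ecg_noise_sd additive ECG noise SD (R-peak amplitude is 1).
#' @param subject_jitter_dprime,subject_jitter_criterion SDs of optional
#'   between-subject jitter of d' and c (0 = homogeneous cohort).
#' @param montage electrode montage data.frame, see [default_montage()].
#' @param seed master integer seed; subject seeds are derived
#'   deterministically from it.
#' @return An object of class `cohort_config` (a validated list).
#' @export
cohort_config <- function(n_subjects = 37L,
                          fs = 250,
                          n_blocks = 8L,
                          stim_trials_per_block = 100L,
                          catch_trials_per_block = 20L,
                          mean_rr = 0.80,
                          sdnn = 0.05,
                          systole_mean = 0.333,
                          systole_sd = 0.021,
                          dprime_systole = 1.48,
                          dprime_diastole = 1.59,
                          criterion_base = 0.76,
                          beta_hep = 0.12,
                          beta_alpha = 0.10,
                          loc_correct_hit = 0.889,
                          loc_correct_miss = 0.570,
                          sep_p300_gain_hit = 1.4,
                          sep_p300_gain_diastole = 1.2,
                          sep_hep_slope = 0.15,
                          phase_mode = c("binary", "smooth"),
                          smooth_dip_amp = 0.3,
                          smooth_dip_width = 0.4,
                          mean_iti = 2.4,
                          rest_duration = 180,
                          signals = c("full", "behavior"),
                          noise_sd = 6,
                          alpha_base = 4,
                          alpha_mod = 0.35,
                          hep_base = 2,
                          hep_scale = 2,
                          sep_p50_amp = 2,
                          sep_n140_amp = -2.5,
                          sep_p300_amp = 3,
                          cfa_amp = 5,
                          ecg_noise_sd = 0.01,
                          subject_jitter_dprime = 0,
                          subject_jitter_criterion = 0,
                          montage = default_montage(),
                          seed = 1L) {
  cfg <- list(
    n_subjects = as.integer(n_subjects), fs = fs,
    n_blocks = as.integer(n_blocks),
    stim_trials_per_block = as.integer(stim_trials_per_block),
    catch_trials_per_block = as.integer(catch_trials_per_block),
    mean_rr = mean_rr, sdnn = sdnn,
    systole_mean = systole_mean, systole_sd = systole_sd,
    dprime_systole = dprime_systole, dprime_diastole = dprime_diastole,
    criterion_base = criterion_base,
    beta_hep = beta_hep, beta_alpha = beta_alpha,
    loc_correct_hit = loc_correct_hit, loc_correct_miss = loc_correct_miss,
    sep_p300_gain_hit = sep_p300_gain_hit,
    sep_p300_gain_diastole = sep_p300_gain_diastole,
    sep_hep_slope = sep_hep_slope,
    phase_mode = match.arg(phase_mode),
    smooth_dip_amp = smooth_dip_amp, smooth_dip_width = smooth_dip_width,
    mean_iti = mean_iti, rest_duration = rest_duration,
    signals = match.arg(signals),
    noise_sd = noise_sd, alpha_base = alpha_base, alpha_mod = alpha_mod,
    hep_base = hep_base, hep_scale = hep_scale,
    sep_p50_amp = sep_p50_amp, sep_n140_amp = sep_n140_amp,
    sep_p300_amp = sep_p300_amp, cfa_amp = cfa_amp,
    ecg_noise_sd = ecg_noise_sd,
    subject_jitter_dprime = subject_jitter_dprime,
    subject_jitter_criterion = subject_jitter_criterion,
    montage = montage, seed = as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  validate_config(cfg)
  cfg
}

#' Validate a cohort configuration
#'
#' Checks the structural invariants of the generative model and stops with an
#' informative message on the first violation.
#'
#' @param config a `cohort_config` object.
#' @return The config, invisibly, if valid.
#' @export
validate_config <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  chk <- function(ok, msg) if (!isTRUE(ok)) stop("invalid config: ", msg, call. = FALSE)
  counts <- c(config$n_subjects, config$n_blocks,
              config$stim_trials_per_block, config$catch_trials_per_block)
  chk(all(counts > 0), "all counts must be > 0")
  probs <- c(config$loc_correct_hit, config$loc_correct_miss)
  chk(all(probs >= 0 & probs <= 1), "probabilities must lie in [0, 1]")
  chk(config$fs > 2 * 45, "fs must exceed twice the highest generated frequency (45 Hz)")
  chk(config$mean_rr > 0 && config$sdnn >= 0, "mean_rr > 0 and sdnn >= 0 required")
  chk(config$systole_mean > 0 && config$systole_sd >= 0, "systole distribution must be positive")
  chk(config$systole_mean < config$mean_rr / 2,
      "systole_mean must be below mean_rr/2 (equal-length diastole must fit)")
  chk(config$mean_iti > 0 && config$rest_duration >= 0, "timing parameters must be positive")
  chk(is.data.frame(config$montage) &&
        all(c("channel", "x", "y", "type") %in% names(config$montage)),
      "montage must have channel/x/y/type columns")
  chk(any(config$montage$type == "eeg"), "montage needs at least one EEG channel")
  invisible(config)
}
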