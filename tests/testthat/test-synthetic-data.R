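test_that("ECG waveform records exact ground-truth t-wave ends", {
  w <- ecg_waveform(rep(0.8, 20), rep(0.333, 20), fs = 500)
  expect_length(w$r_peaks, 20)
  expect_equal(w$t_ends, w$r_peaks + 0.333)
  expect_equal(diff(w$r_peaks), rep(0.8, 19))
  # R spike dominates the trace
  ir <- round(w$r_peaks[5] * w$fs) + 1
  expect_gt(w$samples[ir], 0.9)
  expect_error(ecg_waveform(0.5, 0.6, fs = 500), "shorter")
})

test_that("generation is deterministic given the seed", {
  cfg <- cohort_config(n_subjects = 1, signals = "behavior", seed = 7)
  s1 <- generate_subject(cfg, 99)
  s2 <- generate_subject(cfg, 99)
  expect_identical(s1$trials, s2$trials)
  expect_identical(s1$truth$r_peaks, s2$truth$r_peaks)
  s3 <- generate_subject(cfg, 100)
  expect_false(identical(s1$trials$response_yes, s3$trials$response_yes))
})

test_that("ground truth is complete and internally consistent", {
  s <- generate_subject(cohort_config(n_subjects = 1, signals = "behavior"),
                        321)
  tr <- s$truth$trial
  expect_setequal(
    c("trial", "delay_s", "rr_s", "phase", "dprime", "criterion", "h", "a",
      "sep_scale", "p300_amp"),
    names(tr))
  expect_equal(s$truth$t_end, s$truth$r_peaks[seq_along(s$truth$systole)] +
                 s$truth$systole)
  # phase label matches the delay within the cycle windows
  sys <- tr$phase == "systole"
  expect_true(all(tr$delay_s[sys] < s$truth$systole[
    findInterval(s$trials$onset_s[sys], s$truth$r_peaks)]))
  # binary mode: d' takes the two configured values (plus mid for "neither")
  expect_setequal(unique(tr$dprime[tr$phase == "systole"]), 1.48)
  expect_setequal(unique(tr$dprime[tr$phase == "diastole"]), 1.59)
  # criterion composition
  expect_equal(tr$criterion, 0.76 + 0.12 * tr$h + 0.10 * tr$a)
})

test_that("trial onsets are jittered but never closer than 0.7 s", {
  s <- generate_subject(cohort_config(n_subjects = 1, signals = "behavior"),
                        11)
  expect_gt(min(diff(s$trials$onset_s)), 0.7)
  expect_gt(min(s$trials$onset_s), 0.9)
  expect_lt(max(s$trials$onset_s), max(s$truth$r_peaks))
})

test_that("stimulus onsets are uniform over the cardiac cycle", {
  s <- generate_subject(cohort_config(n_subjects = 1, signals = "behavior"),
                        202)
  cyc <- findInterval(s$trials$onset_s, s$truth$r_peaks)
  ang <- phase_angle(s$trials$onset_s, s$truth$r_peaks[cyc],
                     s$truth$r_peaks[cyc + 1])
  expect_gt(rayleigh_test(ang[s$trials$stim])$rayleigh_p, 0.01)
})

test_that("full-signal mode renders coupled ECG and EEG", {
  s <- small_full_cohort()$subjects[[1]]
  expect_equal(rownames(s$eeg$data), default_montage()$channel)
  expect_equal(ncol(s$eeg$data), length(s$ecg$samples))
  # ECG channel is the scaled ECG trace (plus noise already inside)
  expect_equal(s$eeg$data["ECG", ], s$ecg$samples * 500)
  # alpha ~10 Hz present at C4: bandpower around 10 Hz exceeds 20-Hz flank
  x <- s$eeg$data["C4", 1:2^14]
  sp <- Mod(fft(x))^2
  f <- (seq_along(sp) - 1) * s$eeg$fs / length(sp)
  expect_gt(mean(sp[f > 9 & f < 11]), 2 * mean(sp[f > 19 & f < 21]))
})

test_that("cohort generation derives distinct subject seeds and a summary", {
  coh <- generate_cohort(cohort_config(n_subjects = 5, signals = "behavior",
                                       seed = 2))
  expect_length(coh$subjects, 5)
  expect_equal(anyDuplicated(coh$subject_seeds), 0L)
  expect_equal(nrow(coh$truth_summary), 5)
  expect_output(print(coh), "5 subjects")
})

test_that("config validation rejects impossible settings", {
  expect_error(cohort_config(n_subjects = 0), "counts")
  expect_error(cohort_config(loc_correct_hit = 1.2), "probabilities")
  expect_error(cohort_config(systole_mean = 0.5, mean_rr = 0.8), "systole_mean")
  expect_error(cohort_config(fs = 50), "fs")
})
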