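test_that("preprocess band-limits and average-references the EEG", {
  fs <- 250
  t <- seq(0, 20, by = 1 / fs)[-1]
  dat <- rbind(A = sin(2 * pi * 10 * t), B = sin(2 * pi * 60 * t) + 2,
               ECG = sin(2 * pi * 1 * t))
  pp <- preprocess(dat, fs_in = fs, fs_out = fs, eeg_channels = c("A", "B"),
                   average_ref = FALSE)
  mid <- 1000:4000
  # 10 Hz passes essentially unchanged; 60 Hz and the DC offset are removed
  expect_gt(cor(pp$data["A", mid], dat["A", mid]), 0.99)
  expect_gt(stats::sd(pp$data["A", mid]), 0.6)
  expect_lt(stats::sd(pp$data["B", mid]), 0.05)
  expect_lt(abs(mean(pp$data["B", mid])), 0.05)
  # average reference: EEG rows sum to ~0, ECG row untouched by the reference
  ppr <- preprocess(dat, fs_in = fs, fs_out = fs, eeg_channels = c("A", "B"))
  expect_lt(max(abs(colSums(ppr$data[c("A", "B"), mid]))), 1e-8)
  expect_equal(ppr$data["ECG", ], pp$data["ECG", ])
})

test_that("decimation halves the sampling rate coherently", {
  fs <- 500
  t <- seq(0, 20, by = 1 / fs)[-1]
  dat <- rbind(A = sin(2 * pi * 5 * t), B = cos(2 * pi * 8 * t))
  pp <- preprocess(dat, fs_in = fs, fs_out = 250)
  expect_equal(pp$fs, 250)
  expect_equal(ncol(pp$data), length(t) / 2)
})

test_that("epoching extracts exact half-open windows with baseline removal", {
  fs <- 100
  x <- matrix(seq_len(1000), nrow = 1, dimnames = list("A", NULL))  # ramp
  ep <- epoch_data(x, fs, events = c(5.0), window = c(-0.1, 0.2),
                   baseline = c(-0.1, 0))
  expect_equal(ep$times, seq(-10, 19) / 100)
  # ramp minus its baseline mean: slope 1 per sample around the anchor
  expect_equal(as.numeric(ep$data[1, 1, ]), seq(-10, 19) + 0.5 + 5)
  expect_message(
    ep2 <- epoch_data(x, fs, events = c(0.05, 5), window = c(-0.1, 0.2)),
    "dropped")
  expect_equal(dim(ep2$data)[1], 1)
  expect_error(epoch_data(x, fs, events = 100, window = c(-0.1, 0.2)),
               "coverage")
})

test_that("amplitude bins are equal-count, larger-first, and stable", {
  b <- amplitude_bins(c(5, 1, 4, 2, 3), 2)
  expect_equal(b, c(2L, 1L, 2L, 1L, 1L))        # sizes 3 then 2
  b3 <- amplitude_bins(seq_len(10), 3)
  expect_equal(as.integer(table(b3)), c(4L, 3L, 3L))
  expect_equal(b3[1:4], rep(1L, 4))
  # ties broken by original order (stable sort)
  bt <- amplitude_bins(c(1, 1, 1, 1), 2)
  expect_equal(bt, c(1L, 1L, 2L, 2L))
  expect_error(amplitude_bins(1:2, 3), "n >= n_bins")
})

test_that("phase-matched artifact subtraction cancels a pure artifact", {
  # continuous data = cardiac field artifact only. The template is a
  # phase-conditional mean, so cancellation is a property of condition
  # averages (single epochs keep their delay-specific deviation): with
  # dense uniform onsets the corrected per-phase average must shrink to the
  # 1/sqrt(n) sampling floor, far below the raw artifact average.
  set.seed(7)
  fs <- 250
  rr <- cardioperc:::rtruncnorm(400, 0.8, 0.05, 0.4, 1.2)
  w <- ecg_waveform(rr, rep(0.333, 400), fs)
  dat <- matrix(w$samples * 20, nrow = 1, dimnames = list("Cz", NULL))
  cyc <- build_cycle_table(w$r_peaks, head(w$t_ends, -1))
  onsets <- runif(4000, 20, max(w$r_peaks) - 5)
  templ <- estimate_cardiac_artifact(dat, fs, cyc, stim_onsets = numeric(0),
                                     n_triggers = 4000, seed = 1)
  ph <- classify_phase(onsets, cyc)
  keep <- ph %in% c("systole", "diastole")
  ep <- suppressMessages(
    epoch_data(dat, fs, onsets[keep], window = c(-0.2, 0.6),
               metadata = data.frame(phase = ph[keep])))
  cor <- correct_epochs(ep, templ)
  for (p in c("systole", "diastole")) {
    sel <- ep$metadata$phase == p
    raw_avg <- colMeans(ep$data[sel, 1, ])
    cor_avg <- colMeans(cor$data[sel, 1, ])
    expect_lt(sqrt(mean(cor_avg^2)), 0.15 * sqrt(mean(raw_avg^2)))
  }
  expect_true(all(cor$metadata$artifact_corrected))
})

test_that("HEP epochs enforce the 400-ms delay rule and return rest beats", {
  s <- small_full_cohort()$subjects[[1]]
  r <- s$truth$r_peaks
  cyc <- build_cycle_table(r, s$truth$t_end)
  trials <- annotate_phase(classify_trials(s$trials), cyc)
  hep <- suppressMessages(
    hep_epochs(s$eeg$data, s$eeg$fs, r, trials, cyc))
  expect_true(all(hep$stim$metadata$delay_from_r >= 0.4))
  expect_lt(dim(hep$stim$data)[1], nrow(trials))
  expect_gt(dim(hep$rest$data)[1], 10)
  # every rest beat is far from all stimulus onsets
  expect_true(all(vapply(hep$rest$metadata$r_lock_s, function(rl) {
    min(abs(trials$onset_s - rl)) > 0.3
  }, logical(1))))
})

test_that("component amplitude averages the requested window by condition", {
  fs <- 100
  dat <- matrix(0, 2, 1000, dimnames = list(c("C4", "Pz"), NULL))
  dat[1, 501:520] <- 2                       # 5.00-5.19 s plateau at C4
  ep <- epoch_data(dat, fs, events = c(4.8, 4.9), baseline = NULL,
                   window = c(-0.5, 0.5),
                   metadata = data.frame(grp = c("a", "b")))
  amp <- component_amplitude(ep, "C4", window = c(0.2, 0.4), by = "grp")
  expect_equal(amp$per_trial, c(2, 1))       # full vs half overlap
  expect_equal(amp$condition_means$mean, c(2, 1))
  expect_error(component_amplitude(ep, "XX", window = c(0, 0.1)), "available")
})
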