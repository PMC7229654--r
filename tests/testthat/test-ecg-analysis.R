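test_that("R-peak detection recovers every true beat within 5 ms", {
  s <- full_subject()
  det <- detect_r_peaks(s$ecg)
  expect_equal(length(det), length(s$truth$r_peaks))
  expect_lt(max(abs(det - s$truth$r_peaks)), 0.005)
})

test_that("flat or too-short ECG is handled explicitly", {
  expect_error(detect_r_peaks(rep(0, 100), fs = 250), "10 s")
  expect_warning(out <- detect_r_peaks(rep(0, 5000), fs = 250), "flat")
  expect_identical(out, numeric(0))
})

test_that("trapezoid area maximum sits at the corner of a triangular T wave", {
  # On an ideal descending limb that is linear from the T-peak down to
  # baseline at the corner x_z and flat afterwards, the trapezium area
  # A(x_m) = 0.5 (y_peak - y_m)(2 x_limit - x_m - x_peak) is increasing on
  # the limb (as long as x_limit - x_peak exceeds the limb length) and
  # decreasing on the flat tail, so its maximum is exactly the corner: the
  # true t-wave end.
  fs <- 1000
  t <- seq(0, 2, by = 1 / fs)
  x <- numeric(length(t))
  r_time <- 0.5
  x[round(r_time * fs) + 1] <- 1                     # R spike
  peak_t <- r_time + 0.25                            # T-peak
  corner_t <- peak_t + 0.08                          # true end of the limb
  limb <- t >= peak_t & t <= corner_t
  x[limb] <- 0.3 * (corner_t - t[limb]) / (corner_t - peak_t)
  tw <- twave_end_trapezoid(x, r_peaks = c(r_time, r_time + 1), fs = fs)
  expect_true(tw$valid[1])
  expect_equal(tw$t_peak_s[1], peak_t, tolerance = 2 / fs)
  expect_equal(tw$t_end_s[1], corner_t, tolerance = 2 / fs)
})

test_that("t-wave ends are recovered within tolerance on synthetic ECG", {
  s <- full_subject()
  r <- s$truth$r_peaks
  tw <- twave_end_trapezoid(s$ecg, r)
  ok <- tw$valid
  expect_gt(mean(ok), 0.95)
  err <- tw$t_end_s[ok] - s$truth$t_end[ok]
  expect_lt(mean(abs(err)), 0.012)
  expect_lt(abs(mean(err)), 0.006)
})

test_that("cycle table flags 4-SD systole outliers without dropping rows", {
  set.seed(42)
  r <- seq(0, by = 0.8, length.out = 41)
  t_end <- r[1:40] + 0.33
  t_end[5] <- NA                       # failed detection
  t_end[9] <- r[9] + 0.39              # clear outlier under sd ~ 0.002
  t_end[-c(5, 9)] <- t_end[-c(5, 9)] + rnorm(38, 0, 0.002)
  cyc <- build_cycle_table(r, t_end)
  expect_equal(nrow(cyc), 40)
  expect_false(cyc$valid[5])
  expect_false(cyc$valid[9])
  expect_gt(sum(cyc$valid), 35)
  # systole and diastole windows are equal length, diastole ends at next R
  v <- which(cyc$valid)
  expect_equal(cyc$sys_end_s[v] - cyc$sys_start_s[v],
               cyc$dia_end_s[v] - cyc$dia_start_s[v])
  expect_equal(cyc$dia_end_s, cyc$r_next_s)
  expect_error(build_cycle_table(r[1:4], rep(NA_real_, 3)), "3 valid")
})

test_that("HRV metrics match hand-computed values", {
  rr <- c(0.80, 0.85, 0.78, 0.82, 0.75)
  h <- hrv_metrics(c(0, cumsum(rr)))
  expect_equal(h$mean_hr, 75)
  expect_equal(h$sdnn, 38.0788655293, tolerance = 1e-9)
  expect_equal(h$ln_sdnn, log(h$sdnn))
  h0 <- hrv_metrics(c(0, 0.8, 1.6))
  expect_equal(h0$sdnn, 0)
  expect_true(is.na(h0$ln_sdnn))
})

test_that("cycle tables round-trip through the TSV writer", {
  r <- seq(0, by = 0.8, length.out = 11)
  cyc <- build_cycle_table(r, r[1:10] + 0.33)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cycle_table(cyc, path)
  back <- read.delim(path)
  expect_equal(back$t_end_s, cyc$t_end_s)
  expect_equal(back$valid, cyc$valid)
})
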