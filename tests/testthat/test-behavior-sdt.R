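test_that("SDT measures match the hand-computed log-linear oracle", {
  m <- sdt_measures(7, 3, 1, 9)
  expect_equal(m$hr, 7.5 / 11)
  expect_equal(m$far, 1.5 / 11)
  expect_equal(m$dprime, 1.5695926831, tolerance = 1e-9)
  expect_equal(m$criterion, 0.3120072206, tolerance = 1e-9)
})

test_that("extreme 0 and 100 percent rates stay finite", {
  m0 <- sdt_measures(0, 50, 0, 50)
  m1 <- sdt_measures(50, 0, 50, 0)
  expect_true(all(is.finite(c(m0$dprime, m0$criterion,
                              m1$dprime, m1$criterion))))
  expect_equal(m0$hr, 0.5 / 51)
  expect_equal(m1$far, 50.5 / 51)
  expect_error(sdt_measures(0, 0, 1, 1), "positive")
})

test_that("localization d' follows the sqrt(2) z-rule and guards bounds", {
  expect_equal(localization_dprime(0.889), sqrt(2) * qnorm(0.889))
  expect_equal(localization_dprime(0.5), 0)
  expect_error(localization_dprime(1), "corrected_rate")
  expect_error(localization_dprime(0), "corrected_rate")
  expect_equal(corrected_rate(10, 10), 10.5 / 11)
  expect_equal(corrected_rate(0, 10), 0.5 / 11)
})

test_that("trial classification labels outcomes and localization", {
  tr <- data.frame(
    stim = c(TRUE, TRUE, FALSE, FALSE, TRUE),
    finger = c("index", "middle", NA, NA, "index"),
    response_yes = c(TRUE, FALSE, TRUE, FALSE, NA),
    response_loc = c("index", "index", "middle", "index", NA))
  expect_message(cl <- classify_trials(tr), "1 trial")
  expect_equal(cl$outcome, c("hit", "miss", "fa", "cr", NA))
  expect_equal(cl$loc_correct, c(TRUE, FALSE, NA, NA, NA))
})

test_that("stratified SDT splits counts correctly with per-stratum FAR", {
  tr <- data.frame(
    stim = c(rep(TRUE, 6), rep(FALSE, 4)),
    finger = c(rep("index", 6), rep(NA, 4)),
    response_yes = c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE,
                     TRUE, FALSE, FALSE, FALSE),
    response_loc = c("index", "middle", NA, "index", NA, NA,
                     NA, NA, NA, NA),
    phase = c("systole", "systole", "systole", "diastole", "diastole",
              "diastole", "systole", "systole", "diastole", "diastole"))
  s <- sdt_by_stratum(classify_trials(tr), "phase")
  sys <- s[s$stratum == "systole", ]
  expect_equal(c(sys$n_hit, sys$n_miss, sys$n_fa, sys$n_cr), c(2, 1, 1, 1))
  expect_equal(sys$rate, 2 / 3)
  expect_equal(sys$far, 1.5 / 3)
  expect_equal(sys$loc_rate, 1 / 2)
  all_s <- sdt_by_stratum(classify_trials(tr))
  expect_equal(all_s$n_hit + all_s$n_miss, 6)
})

test_that("SDT round trip is unbiased at the default trial counts", {
  # Monte Carlo calibration: with 800/160 trials per subject, the mean
  # recovered d' and c over replicates stay within the generative values
  cfg <- cohort_config(n_subjects = 1, signals = "behavior",
                       dprime_systole = 1.57, dprime_diastole = 1.57,
                       beta_hep = 0, beta_alpha = 0)
  est <- vapply(1:40, function(i) {
    s <- generate_subject(cfg, 1000 + i)
    m <- sdt_by_stratum(classify_trials(s$trials))
    c(m$dprime, m$criterion)
  }, numeric(2))
  expect_equal(mean(est[1, ]), 1.57, tolerance = 0.05)
  expect_equal(mean(est[2, ]), 0.76, tolerance = 0.04)
})
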