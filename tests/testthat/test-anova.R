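# Independent oracles: F ratio against stats::aov, Greenhouse-Geisser
# epsilon against the textbook covariance formula.

gg_epsilon_oracle <- function(y) {
  p <- ncol(y)
  S <- stats::cov(y)
  # orthonormal contrast basis (Helmert, normalized)
  C <- stats::contr.helmert(p)
  C <- apply(C, 2, function(v) v / sqrt(sum(v^2)))
  E <- t(C) %*% S %*% C
  sum(diag(E))^2 / ((p - 1) * sum(E^2))
}

test_that("one-factor F and p match the aov oracle", {
  set.seed(21)
  n <- 16; p <- 4
  y <- matrix(rnorm(n * p), n, p) + matrix(rep(c(0, 0.3, 0.1, 0.5), each = n),
                                           n, p)
  res <- rm_anova_gg(y, data.frame(cond = letters[1:p]))
  df <- data.frame(y = as.vector(y),
                   cond = factor(rep(letters[1:p], each = n)),
                   subj = factor(rep(seq_len(n), p)))
  fit <- summary(stats::aov(y ~ cond + Error(subj / cond), data = df))
  tab <- fit[["Error: subj:cond"]][[1]]
  expect_equal(res$F, tab["cond", "F value"], tolerance = 1e-8)
  expect_equal(res$p_uncorrected, tab["cond", "Pr(>F)"], tolerance = 1e-8)
  expect_equal(res$df1, 3)
  expect_equal(res$df2, 45)
})

test_that("GG epsilon matches the covariance formula when correction fires", {
  set.seed(22)
  n <- 24; p <- 4
  # strongly heteroscedastic, correlated conditions: sphericity violated
  base <- rnorm(n)
  y <- cbind(base + rnorm(n, sd = 0.1),
             base + rnorm(n, sd = 0.1) + 0.2,
             rnorm(n, sd = 2),
             rnorm(n, sd = 3) + 0.5)
  res <- rm_anova_gg(y, data.frame(cond = letters[1:4]))
  expect_true(res$corrected)
  expect_lt(res$sphericity_p, 0.05)
  expect_equal(res$epsilon, gg_epsilon_oracle(y), tolerance = 1e-6)
  expect_equal(res$df1_gg, 3 * res$epsilon)
  # corrected p equals the F tail at the adjusted dfs
  expect_equal(res$p,
               pf(res$F, res$df1_gg, res$df2_gg, lower.tail = FALSE),
               tolerance = 1e-8)
})

test_that("two-level effects are never epsilon-corrected", {
  set.seed(23)
  y <- matrix(rnorm(30), 15, 2)
  res <- rm_anova_gg(y, data.frame(cond = c("x", "y")))
  expect_equal(res$epsilon, 1)
  expect_false(res$corrected)
})

test_that("two crossed factors return all three effects", {
  set.seed(24)
  within <- expand.grid(phase = c("sys", "dia"), bin = paste0("q", 1:5))
  y <- matrix(rnorm(12 * 10), 12, 10) +
    matrix(rep(ifelse(within$phase == "dia", 0.8, 0), each = 12), 12, 10)
  res <- rm_anova_gg(y, within)
  expect_setequal(res$effect, c("phase", "bin", "phase:bin"))
  expect_lt(res$p[res$effect == "phase"], 0.01)
  expect_gt(res$p[res$effect == "phase:bin"], 0.05)
})

test_that("degenerate and malformed input is handled", {
  y <- matrix(5, 10, 3)
  res <- rm_anova_gg(y, data.frame(cond = letters[1:3]))
  expect_equal(res$F, 0)
  expect_equal(res$p, 1)
  yna <- matrix(rnorm(30), 10, 3)
  yna[2, 2] <- NA
  expect_error(rm_anova_gg(yna, data.frame(cond = letters[1:3])), "complete")
  expect_error(rm_anova_gg(matrix(rnorm(30), 10, 3),
                           data.frame(cond = letters[1:4])))
})
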