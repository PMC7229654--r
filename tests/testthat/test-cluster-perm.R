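test_that("neighbourhood graphs are symmetric without self-edges", {
  mont <- default_montage()
  nb <- build_neighbours(mont[mont$type == "eeg", ])
  expect_s3_class(nb, "adjacency_graph")
  for (ch in nb$channels) {
    expect_false(ch %in% nb$neighbours[[ch]])
    for (other in nb$neighbours[[ch]]) {
      expect_true(ch %in% nb$neighbours[[other]])
    }
  }
  # the default montage is fully usable: every electrode has 2-6 neighbours
  deg <- lengths(nb$neighbours)
  expect_true(all(deg >= 2 & deg <= 6))
  expect_warning(build_neighbours(data.frame(channel = c("a", "b"),
                                             x = c(0, 0), y = c(0, 10)),
                                  threshold = 1),
                 "isolated")
})

test_that("cluster labelling merges runs across adjacent channels only", {
  mask <- rbind(c(TRUE, TRUE, FALSE, TRUE),
                c(FALSE, TRUE, FALSE, FALSE),
                c(TRUE, FALSE, FALSE, TRUE))
  # chain adjacency 1-2, 2-3
  adj <- list(2L, c(1L, 3L), 2L)
  cl <- cardioperc:::label_clusters(mask, adj)
  sizes <- sort(unname(vapply(cl, length, integer(1))))
  # {(1,1),(1,2),(2,2)} merge; (1,4) alone; (3,1) alone; (3,4) alone
  expect_equal(sizes, c(1L, 1L, 1L, 3L))
  # with no adjacency, channels never merge
  cl0 <- cardioperc:::label_clusters(mask, list(integer(0), integer(0),
                                                integer(0)))
  expect_equal(sort(unname(vapply(cl0, length, integer(1)))),
               c(1L, 1L, 1L, 1L, 2L))
})

test_that("the pointwise t statistics match t.test", {
  set.seed(10)
  a <- matrix(rnorm(12 * 20), 12, 20)
  b <- matrix(rnorm(12 * 20), 12, 20)
  res <- paired_cluster_test(a, b, n_perm = 100, seed = 1)
  for (j in c(1, 7, 20)) {
    expect_equal(res$t_obs[1, j],
                 unname(t.test(a[, j], b[, j], paired = TRUE)$statistic),
                 tolerance = 1e-10)
  }
  expect_equal(res$t_crit, qt(0.975, 11))
})

test_that("identical conditions yield no clusters and p is never zero", {
  set.seed(11)
  a <- matrix(rnorm(10 * 30), 10, 30)
  res <- paired_cluster_test(a, a, n_perm = 200, seed = 2)
  expect_equal(nrow(res$clusters), 0L)
  set.seed(12)
  b <- a + matrix(rnorm(10 * 30, 0, 0.1), 10, 30)
  res2 <- paired_cluster_test(a, b, n_perm = 200, seed = 2)
  if (nrow(res2$clusters) > 0) {
    expect_true(all(res2$clusters$p > 0))
    expect_true(all(res2$clusters$p >= 1 / 201))
  }
})

test_that("an injected space-time effect is recovered at the right site", {
  set.seed(13)
  n_sub <- 14; n_ch <- 4; n_t <- 60
  channels <- c("A", "B", "C", "D")
  pos <- data.frame(channel = channels, x = c(0, 1, 0, 5), y = c(0, 0, 1, 5))
  nb <- build_neighbours(pos, threshold = 1.5)
  a <- array(rnorm(n_sub * n_ch * n_t), c(n_sub, n_ch, n_t))
  b <- array(rnorm(n_sub * n_ch * n_t), c(n_sub, n_ch, n_t))
  b[, 1:2, 21:35] <- b[, 1:2, 21:35] + 1.6          # effect at A+B only
  times <- seq(0, by = 0.01, length.out = n_t)
  res <- paired_cluster_test(a, b, neighbours = nb, channels = channels,
                             times = times, n_perm = 500, seed = 3)
  expect_gt(nrow(res$clusters), 0)
  top <- res$clusters[1, ]
  expect_true(top$significant)
  expect_equal(top$sign, -1)                         # a < b
  # the injected channels must participate; the far-away channel must not
  # (a noisy neighbour of the true cluster may legitimately join it)
  expect_true(all(c("A", "B") %in% cluster_channels(res)))
  expect_false("D" %in% cluster_channels(res))
  expect_lt(abs(top$t_start - 0.20), 0.05)
  expect_lt(abs(top$t_end - 0.34), 0.05)
  # deterministic under the same seed
  res2 <- paired_cluster_test(a, b, neighbours = nb, channels = channels,
                              times = times, n_perm = 500, seed = 3)
  expect_identical(res$clusters, res2$clusters)
})

test_that("degenerate and undersized inputs are rejected or neutral", {
  a <- matrix(rnorm(5 * 10), 5, 10)
  expect_error(paired_cluster_test(a, a, n_perm = 100), "6")
  # constant differences have zero variance: t is defined as 0, no clusters
  a <- matrix(rnorm(8 * 10), 8, 10)
  res <- paired_cluster_test(a, a + 2, n_perm = 100, seed = 1)
  expect_equal(nrow(res$clusters), 0L)
  expect_true(all(res$t_obs == 0))
})
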