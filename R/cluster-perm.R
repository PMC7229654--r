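# Nonparametric cluster-based permutation testing for paired two-condition
# comparisons over time (one channel) or space x time.

#' Build a channel neighbourhood graph from 2D positions
#'
#' Channels whose Euclidean distance is at most `threshold` are neighbours;
#' the default threshold is 1.5 times the median nearest-neighbour distance.
#' The graph is symmetric with no self-neighbours.
#'
#' @param positions data.frame with `channel`, `x`, `y` columns (e.g. a
#'   montage restricted to EEG channels) or a 2-column matrix with rownames.
#' @param threshold neighbour distance threshold; NULL for the default rule.
#' @return list of class `adjacency_graph`: `channels`, `neighbours` (named
#'   list of character vectors), `threshold`.
#' @export
build_neighbours <- function(positions, threshold = NULL) {
  if (is.data.frame(positions)) {
    ch <- positions$channel
    xy <- as.matrix(positions[, c("x", "y")])
  } else {
    ch <- rownames(positions)
    xy <- positions
  }
  n <- length(ch)
  if (n < 2L) stop("need at least 2 channels")
  d <- as.matrix(dist(xy))
  diag(d) <- Inf
  if (is.null(threshold)) threshold <- 1.5 * median(apply(d, 1, min))
  nb <- lapply(seq_len(n), function(i) ch[d[i, ] <= threshold])
  names(nb) <- ch
  if (all(lengths(nb) == 0L)) warning("threshold yields an isolated graph")
  structure(list(channels = ch, neighbours = nb, threshold = threshold),
            class = "adjacency_graph")
}

# Label connected components of a logical channels x time mask under
# (channel-graph x consecutive-sample) adjacency. Returns a list of integer
# vectors of flat indices (column-major, as in which(mask)).
label_clusters <- function(mask, adj_idx) {
  n_ch <- nrow(mask)
  n_t <- ncol(mask)
  # runs of TRUE per channel
  run_ch <- integer(0); run_lo <- integer(0); run_hi <- integer(0)
  for (c in seq_len(n_ch)) {
    r <- rle(mask[c, ])
    if (!any(r$values)) next
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    sel <- which(r$values)
    run_ch <- c(run_ch, rep.int(c, length(sel)))
    run_lo <- c(run_lo, starts[sel])
    run_hi <- c(run_hi, ends[sel])
  }
  n_run <- length(run_ch)
  if (n_run == 0L) return(list())
  parent <- seq_len(n_run)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  ord <- order(run_ch)
  by_ch <- split(ord, run_ch[ord])          # run indices per channel
  for (c in seq_len(n_ch)) {
    rc <- by_ch[[as.character(c)]]
    if (is.null(rc)) next
    for (nb in adj_idx[[c]]) {
      if (nb <= c) next                     # each edge once
      rn <- by_ch[[as.character(nb)]]
      if (is.null(rn)) next
      for (i in rc) {
        for (j in rn) {
          if (run_lo[i] <= run_hi[j] && run_lo[j] <= run_hi[i]) {
            ri <- find(i); rj <- find(j)
            if (ri != rj) parent[ri] <- rj
          }
        }
      }
    }
  }
  roots <- vapply(seq_len(n_run), find, integer(1))
  groups <- split(seq_len(n_run), roots)
  lapply(groups, function(g) {
    unlist(lapply(g, function(i) {
      (seq.int(run_lo[i], run_hi[i]) - 1L) * n_ch + run_ch[i]
    }), use.names = FALSE)
  })
}

# Cluster masses (sum of t) for both signs; returns numeric vector (possibly
# empty) of signed masses, plus optionally the member indices.
cluster_masses <- function(tmat, tcrit, adj_idx, members = FALSE) {
  out_mass <- numeric(0)
  out_members <- list()
  out_sign <- integer(0)
  for (sgn in c(1, -1)) {
    mask <- if (sgn > 0) tmat > tcrit else tmat < -tcrit
    if (!any(mask)) next
    cl <- label_clusters(mask, adj_idx)
    if (length(cl) == 0L) next
    m <- vapply(cl, function(ix) sum(tmat[ix]), numeric(1))
    out_mass <- c(out_mass, m)
    out_sign <- c(out_sign, rep.int(sgn, length(m)))
    if (members) out_members <- c(out_members, cl)
  }
  list(mass = out_mass, sign = out_sign, members = out_members)
}

#' Paired cluster-based permutation test
#'
#' Computes a paired t statistic at every (channel, time) point, clusters
#' suprathreshold points of equal sign under channel-neighbourhood x
#' consecutive-sample adjacency, sums t values within clusters (the cluster
#' mass), and evaluates each observed mass against the permutation null
#' distribution of the maximum absolute cluster mass obtained by randomly
#' sign-flipping the within-subject condition differences. The two-tailed
#' Monte Carlo p is (1 + #{perm max >= |observed mass|}) / (n_perm + 1),
#' never zero.
#'
#' @param cond_a,cond_b subjects x channels x time arrays (or subjects x
#'   time matrices for a single channel), matched by subject.
#' @param neighbours an [build_neighbours()] graph, or NULL for temporal-only
#'   clustering (all channels treated as one-node graphs is wrong -- NULL
#'   means no cross-channel adjacency, which for one channel is the
#'   temporal-only mode).
#' @param channels channel names (default from dimnames or `"ch1"`, ...).
#' @param times optional time axis (s), carried into the cluster report.
#' @param n_perm number of sign-flip permutations (warning below 100).
#' @param cluster_alpha cluster-forming threshold: points with |t| above the
#'   two-sided t quantile at this level enter clusters.
#' @param alpha cluster-level significance level.
#' @param seed optional RNG seed for reproducible permutations.
#' @return list of class `cluster_result`: `clusters` (data.frame with sign,
#'   mass, n_points, p, significant, time extent), `members` (list of
#'   channel/time index matrices), `t_obs`, `t_crit`, `null_max`,
#'   `n_perm`, `alpha`.
#' @export
paired_cluster_test <- function(cond_a, cond_b, neighbours = NULL,
                                channels = NULL, times = NULL,
                                n_perm = 1000, cluster_alpha = 0.05,
                                alpha = 0.05, seed = NULL) {
  if (length(dim(cond_a)) == 2L) {
    cond_a <- array(cond_a, dim = c(nrow(cond_a), 1L, ncol(cond_a)))
    cond_b <- array(cond_b, dim = c(nrow(cond_b), 1L, ncol(cond_b)))
  }
  if (!identical(dim(cond_a), dim(cond_b))) stop("condition arrays differ in shape")
  n_sub <- dim(cond_a)[1]
  n_ch <- dim(cond_a)[2]
  n_t <- dim(cond_a)[3]
  if (n_sub < 6L) stop("need at least 6 matched subjects")
  if (n_perm < 100) warning("fewer than 100 permutations: p resolution is coarse")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(channels)) {
    channels <- dimnames(cond_a)[[2]] %||% paste0("ch", seq_len(n_ch))
  }
  # channel adjacency as integer index lists
  if (is.null(neighbours)) {
    adj_idx <- rep(list(integer(0)), n_ch)
  } else {
    adj_idx <- lapply(channels, function(ch) {
      ix <- match(intersect(neighbours$neighbours[[ch]], channels), channels)
      ix[!is.na(ix)]
    })
  }
  diffs <- matrix(cond_a - cond_b, nrow = n_sub)   # n_sub x (ch*time), ch fastest
  mu <- colMeans(diffs)
  ss <- colSums(diffs^2)
  vr <- (ss - n_sub * mu^2) / (n_sub - 1)
  se <- sqrt(pmax(vr, 0) / n_sub)
  tvec <- ifelse(se > 0, mu / se, 0)
  tmat <- matrix(tvec, n_ch, n_t)
  tcrit <- qt(1 - cluster_alpha / 2, df = n_sub - 1)
  obs <- cluster_masses(tmat, tcrit, adj_idx, members = TRUE)

  null_max <- numeric(n_perm)
  for (p in seq_len(n_perm)) {
    s <- sample(c(-1, 1), n_sub, replace = TRUE)
    mu_p <- as.numeric(crossprod(s, diffs)) / n_sub
    vr_p <- (ss - n_sub * mu_p^2) / (n_sub - 1)
    se_p <- sqrt(pmax(vr_p, 0) / n_sub)
    t_p <- matrix(ifelse(se_p > 0, mu_p / se_p, 0), n_ch, n_t)
    cm <- cluster_masses(t_p, tcrit, adj_idx, members = FALSE)
    null_max[p] <- if (length(cm$mass) > 0) max(abs(cm$mass)) else 0
  }

  k <- length(obs$mass)
  clusters <- data.frame(cluster = integer(0), sign = integer(0),
                         mass = numeric(0), n_points = integer(0),
                         p = numeric(0), significant = logical(0),
                         t_start = numeric(0), t_end = numeric(0))
  members <- list()
  if (k > 0) {
    pvals <- vapply(obs$mass, function(m) {
      (1 + sum(null_max >= abs(m))) / (n_perm + 1)
    }, numeric(1))
    ord <- order(-abs(obs$mass))
    ext <- lapply(obs$members, function(ix) {
      chp <- ((ix - 1L) %% n_ch) + 1L
      tp <- ((ix - 1L) %/% n_ch) + 1L
      cbind(channel = chp, time = tp)
    })
    clusters <- data.frame(
      cluster = seq_len(k),
      sign = obs$sign[ord],
      mass = obs$mass[ord],
      n_points = vapply(ext[ord], nrow, integer(1)),
      p = pvals[ord],
      significant = pvals[ord] < alpha
    )
    clusters$t_start <- vapply(ext[ord], function(e) {
      if (is.null(times)) min(e[, "time"]) else times[min(e[, "time"])]
    }, numeric(1))
    clusters$t_end <- vapply(ext[ord], function(e) {
      if (is.null(times)) max(e[, "time"]) else times[max(e[, "time"])]
    }, numeric(1))
    members <- ext[ord]
  }
  structure(list(clusters = clusters, members = members,
                 t_obs = tmat, t_crit = tcrit, null_max = null_max,
                 n_perm = n_perm, alpha = alpha,
                 channels = channels, times = times),
            class = "cluster_result")
}

#' Channels participating in significant clusters
#'
#' @param result a `cluster_result`.
#' @return character vector of channel names in any significant cluster
#'   (empty when none).
#' @export
cluster_channels <- function(result) {
  sig <- which(result$clusters$significant)
  if (length(sig) == 0L) return(character(0))
  unique(result$channels[unlist(lapply(result$members[sig],
                                       function(e) e[, "channel"]))])
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("<cluster_result>", nrow(x$clusters), "cluster(s),",
      sum(x$clusters$significant), "significant at alpha =", x$alpha, "\n")
  if (nrow(x$clusters) > 0) print(x$clusters, row.names = FALSE)
  invisible(x)
}
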