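# Cohort orchestration: per-subject preparation, group statistics for every
# analysis family (phase, SEP, HEP, alpha, controls), and the assembled
# report.

paired_t_row <- function(contrast, a, b) {
  tt <- stats::t.test(a, b, paired = TRUE)
  data.frame(contrast = contrast, mean_a = mean(a), mean_b = mean(b),
             t = unname(tt$statistic), df = unname(tt$parameter),
             p = tt$p.value)
}

#' Per-subject preparation for the group pipeline
#'
#' Runs the single-subject chain once: R-peak detection, trapezoid t-wave
#' ends, cycle table, outcome classification and phase annotation, HRV; and
#' in full-signal mode additionally: band filtering + average reference,
#' random-trigger cardiac-artifact templates, artifact-corrected
#' stimulus-locked epochs (kept at C4 and the ECG channel), R-locked HEP
#' epochs (stimulus-preceding and resting beats, kept over a -0.1 to 0.6 s
#' subwindow across all EEG channels), and per-trial prestimulus alpha.
#'
#' @param sd a `subject_dataset`.
#' @param seed RNG seed for artifact-trigger placement.
#' @param n_triggers random triggers for the artifact estimate; defaults to
#'   the trial count.
#' @param alpha_channel sensorimotor channel for alpha extraction.
#' @return list of per-subject intermediates consumed by the `run_*`
#'   analyses.
#' @export
prepare_subject <- function(sd, seed = sd$subject_seed, n_triggers = NULL,
                            alpha_channel = "C4") {
  stopifnot(inherits(sd, "subject_dataset"))
  full <- !is.null(sd$eeg)
  if (full) {
    r_peaks <- detect_r_peaks(sd$ecg)
    tw <- twave_end_trapezoid(sd$ecg, r_peaks)
    cycles <- build_cycle_table(r_peaks, tw$t_end_s)
  } else {
    r_peaks <- sd$truth$r_peaks
    cycles <- build_cycle_table(r_peaks, sd$truth$t_end)
  }
  trials <- annotate_phase(classify_trials(sd$trials), cycles)
  out <- list(trials = trials, cycles = cycles, r_peaks = r_peaks,
              hrv = hrv_metrics(r_peaks), full = full,
              montage = sd$config$montage)
  if (!full) return(out)

  fs <- sd$eeg$fs
  pp <- preprocess(sd$eeg$data, fs_in = fs, fs_out = fs)
  dat <- pp$data
  if (is.null(n_triggers)) n_triggers <- nrow(trials)
  templ <- estimate_cardiac_artifact(dat, fs, cycles,
                                     stim_onsets = trials$onset_s,
                                     n_triggers = n_triggers, seed = seed)
  ep <- epoch_data(dat, fs, trials$onset_s, window = c(-1, 2),
                   baseline = c(-0.1, 0), metadata = trials)
  ep <- correct_epochs(ep, templ)
  out$alpha_trial <- prestim_alpha(ep, channel = alpha_channel)
  c4 <- match("C4", ep$channels)
  ecg_ch <- match("ECG", ep$channels)
  out$sep_times <- ep$times
  out$sep_trial_c4 <- ep$data[, c4, ]
  out$sep_trial_ecg <- if (!is.na(ecg_ch)) ep$data[, ecg_ch, ] else NULL
  out$sep_meta <- ep$metadata
  rm(ep)

  hep <- hep_epochs(dat, fs, r_peaks, trials, cycles)
  keep_t <- which(hep$stim$times >= -0.1 & hep$stim$times < 0.6)
  eeg_ch <- out$montage$channel[out$montage$type == "eeg"]
  eidx <- match(eeg_ch, hep$stim$channels)
  out$hep_times <- hep$stim$times[keep_t]
  out$hep_channels <- eeg_ch
  out$hep_trial <- hep$stim$data[, eidx, keep_t, drop = FALSE]
  out$hep_meta <- hep$stim$metadata
  if (!is.na(ecg_ch)) {
    out$ecg_hep_trial <- hep$stim$data[, match("ECG", hep$stim$channels),
                                       keep_t]
  }
  if (!is.null(hep$rest)) {
    out$hep_rest <- hep$rest$data[, eidx, keep_t, drop = FALSE]
  }
  out
}

#' Prepare every subject of a cohort
#'
#' @param cohort a [generate_cohort()] result (or list of
#'   `subject_dataset`s).
#' @param seed master seed for per-subject artifact-trigger placement.
#' @param ... passed to [prepare_subject()].
#' @return list of class `prepared_cohort`.
#' @export
prepare_cohort <- function(cohort, seed = NULL, ...) {
  subjects <- if (inherits(cohort, "cohort")) cohort$subjects else cohort
  if (is.null(seed) && inherits(cohort, "cohort")) seed <- cohort$config$seed
  prep <- lapply(seq_along(subjects), function(i) {
    prepare_subject(subjects[[i]], seed = derive_seed(seed %||% 1L, i), ...)
  })
  class(prep) <- "prepared_cohort"
  prep
}

as_prepared <- function(cohort, ...) {
  if (inherits(cohort, "prepared_cohort")) cohort else prepare_cohort(cohort, ...)
}

# Per-subject SDT rows for systole/diastole with a minimum-trial rule.
phase_sdt_subject <- function(trials, min_trials = 10L) {
  ph <- trials[trials$phase %in% c("systole", "diastole"), , drop = FALSE]
  ph$phase <- factor(ph$phase, levels = c("systole", "diastole"))
  s <- sdt_by_stratum(ph, "phase")
  if (any(s$n_hit + s$n_miss < min_trials)) return(NULL)
  s
}

#' Cardiac-phase analysis of a cohort
#'
#' Per-subject detection/localization rates and SDT measures by
#' systole/diastole (with phase-specific false-alarm rates) compared with
#' paired t tests; delay-bin (0-200/200-400/400-600/600-800 ms) ANOVAs with
#' adjacent-bin post hoc t tests; circular statistics per outcome (subjects
#' whose stimulation onsets fail the Rayleigh uniformity check at p < 0.05
#' are excluded from circular analyses); and correlations of heart rate and
#' ln-SDNN HRV with the diastole-systole detection difference.
#'
#' @param cohort a cohort or `prepared_cohort`.
#' @param min_trials per-stratum minimum stimulation-trial count; subjects
#'   below it are excluded from that contrast.
#' @return list report section.
#' @export
run_phase_analysis <- function(cohort, min_trials = 10L) {
  prep <- as_prepared(cohort)
  if (length(prep) < 6L) stop("need at least 6 subjects")

  per_subj <- list()
  excluded_phase <- integer(0)
  for (i in seq_along(prep)) {
    s <- phase_sdt_subject(prep[[i]]$trials, min_trials)
    if (is.null(s)) { excluded_phase <- c(excluded_phase, i); next }
    s$subject <- i
    per_subj[[length(per_subj) + 1L]] <- s
  }
  subj_tab <- do.call(rbind, per_subj)
  sys <- subj_tab[subj_tab$stratum == "systole", ]
  dia <- subj_tab[subj_tab$stratum == "diastole", ]
  phase_tests <- rbind(
    paired_t_row("detection_rate", sys$rate, dia$rate),
    paired_t_row("false_alarm_rate", sys$far, dia$far),
    paired_t_row("dprime", sys$dprime, dia$dprime),
    paired_t_row("criterion", sys$criterion, dia$criterion),
    paired_t_row("loc_rate", sys$loc_rate, dia$loc_rate),
    paired_t_row("loc_dprime", sys$loc_dprime, dia$loc_dprime)
  )

  # delay bins
  bins <- c("0-200", "200-400", "400-600", "600-800")
  delay_mats <- list(rate = NULL, dprime = NULL, criterion = NULL,
                     loc_rate = NULL)
  rows <- lapply(seq_along(prep), function(i) {
    tr <- prep[[i]]$trials
    tr <- tr[tr$delay_bin %in% bins, , drop = FALSE]
    tr$delay_bin <- factor(tr$delay_bin, levels = bins)
    s <- sdt_by_stratum(tr, "delay_bin")
    if (any(s$n_hit + s$n_miss < min_trials)) return(NULL)
    s
  })
  keep <- !vapply(rows, is.null, logical(1))
  for (m in names(delay_mats)) {
    delay_mats[[m]] <- do.call(rbind, lapply(rows[keep], function(s) s[[m]]))
  }
  within <- data.frame(bin = bins)
  delay_anova <- lapply(delay_mats, rm_anova_gg, within = within)
  posthoc <- do.call(rbind, lapply(1:3, function(k) {
    rbind(
      paired_t_row(paste0("rate ", bins[k], " vs ", bins[k + 1]),
                   delay_mats$rate[, k], delay_mats$rate[, k + 1]),
      paired_t_row(paste0("dprime ", bins[k], " vs ", bins[k + 1]),
                   delay_mats$dprime[, k], delay_mats$dprime[, k + 1]),
      paired_t_row(paste0("loc_rate ", bins[k], " vs ", bins[k + 1]),
                   delay_mats$loc_rate[, k], delay_mats$loc_rate[, k + 1])
    )
  }))

  # circular analysis: subject-level uniformity gate, then group Rayleigh on
  # per-subject mean angles per outcome
  circ_excluded <- integer(0)
  outcomes <- list(hit = quote(outcome == "hit"),
                   miss = quote(outcome == "miss"),
                   loc_correct = quote(stim & loc_correct %in% TRUE),
                   loc_wrong = quote(stim & loc_correct %in% FALSE))
  mean_angles <- matrix(NA_real_, length(prep), length(outcomes),
                        dimnames = list(NULL, names(outcomes)))
  for (i in seq_along(prep)) {
    tr <- prep[[i]]$trials
    ang <- tr$angle[tr$stim & !is.na(tr$angle)]
    unif <- rayleigh_test(ang)
    if (unif$rayleigh_p < 0.05) { circ_excluded <- c(circ_excluded, i); next }
    for (o in names(outcomes)) {
      sel <- eval(outcomes[[o]], tr) & !is.na(tr$angle)
      if (sum(sel, na.rm = TRUE) >= 1) {
        mean_angles[i, o] <- circular_mean(tr$angle[which(sel)])$mean_angle
      }
    }
  }
  circular <- lapply(names(outcomes), function(o) {
    ang <- mean_angles[!is.na(mean_angles[, o]), o]
    if (length(ang) < 4L) return(NULL)
    rayleigh_test(ang)
  })
  names(circular) <- names(outcomes)

  # HR / HRV correlations with the phase effect on detection
  diff_rate <- dia$rate - sys$rate
  hr <- vapply(prep, function(p) p$hrv$mean_hr, numeric(1))
  ln_sdnn <- vapply(prep, function(p) p$hrv$ln_sdnn, numeric(1))
  inc <- setdiff(seq_along(prep), excluded_phase)
  cor_hr <- stats::cor.test(hr[inc], diff_rate)
  cor_hrv <- stats::cor.test(ln_sdnn[inc], diff_rate)

  list(per_subject = subj_tab,
       phase_tests = phase_tests,
       delay = list(means = lapply(delay_mats, colMeans),
                    anova = delay_anova, posthoc = posthoc, bins = bins),
       circular = list(group = circular, mean_angles = mean_angles,
                       excluded_subjects = circ_excluded),
       correlations = data.frame(
         measure = c("heart_rate", "ln_sdnn"),
         r = c(unname(cor_hr$estimate), unname(cor_hrv$estimate)),
         p = c(cor_hr$p.value, cor_hrv$p.value)),
       excluded_subjects = excluded_phase,
       n = length(inc))
}

# subject-level condition mean of a trials x time matrix
cond_mean <- function(mat, sel) {
  if (sum(sel) == 0L) return(rep(NA_real_, ncol(mat)))
  colMeans(mat[sel, , drop = FALSE])
}

#' SEP analysis: systole vs diastole and detection effects
#'
#' Temporal cluster-based permutation tests at the contralateral
#' somatosensory electrode (C4) over 0-600 ms post-stimulus on
#' artifact-corrected SEPs: systole vs diastole over all stimulation trials,
#' within hits, and within misses; plus a 2 x 2 within-subject ANOVA
#' (detection x cardiac phase) on the mean P300 amplitude 268-468 ms.
#'
#' @param cohort a cohort or `prepared_cohort` (full-signal mode).
#' @param n_perm permutations per cluster test.
#' @param seed RNG seed for the permutations.
#' @return list report section.
#' @export
run_sep_analysis <- function(cohort, n_perm = 1000, seed = 1L) {
  prep <- as_prepared(cohort)
  stopifnot(prep[[1]]$full)
  times <- prep[[1]]$sep_times
  widx <- which(times >= 0 & times < 0.6)
  wt <- times[widx]
  conds <- list(
    sys = function(md) md$stim & md$phase == "systole",
    dia = function(md) md$stim & md$phase == "diastole",
    hit_sys = function(md) md$outcome %in% "hit" & md$phase == "systole",
    hit_dia = function(md) md$outcome %in% "hit" & md$phase == "diastole",
    miss_sys = function(md) md$outcome %in% "miss" & md$phase == "systole",
    miss_dia = function(md) md$outcome %in% "miss" & md$phase == "diastole"
  )
  avg <- lapply(conds, function(f) {
    t(vapply(prep, function(p) {
      cond_mean(p$sep_trial_c4[, widx, drop = FALSE], f(p$sep_meta))
    }, numeric(length(widx))))
  })
  pct <- function(a, b, s) {
    ok <- stats::complete.cases(a) & stats::complete.cases(b)
    paired_cluster_test(a[ok, , drop = FALSE], b[ok, , drop = FALSE],
                        times = wt, n_perm = n_perm,
                        seed = derive_seed(seed, s))
  }
  cl_all <- pct(avg$sys, avg$dia, 1)
  cl_hit <- pct(avg$hit_sys, avg$hit_dia, 2)
  cl_miss <- pct(avg$miss_sys, avg$miss_dia, 3)
  # P300 ANOVA (detection x phase), mean amplitude 268-468 ms
  p300_idx <- which(wt >= 0.268 & wt < 0.468)
  cells <- c("hit_sys", "hit_dia", "miss_sys", "miss_dia")
  p300 <- vapply(cells, function(cn) rowMeans(avg[[cn]][, p300_idx]),
                 numeric(length(prep)))
  ok <- stats::complete.cases(p300)
  within <- data.frame(detection = c("hit", "hit", "miss", "miss"),
                       phase = c("sys", "dia", "sys", "dia"))
  p300_anova <- rm_anova_gg(p300[ok, , drop = FALSE], within)
  list(times = wt,
       grand_average = lapply(avg, colMeans, na.rm = TRUE),
       cluster_sys_vs_dia = cl_all,
       cluster_hits = cl_hit, cluster_misses = cl_miss,
       p300 = list(cell_means = colMeans(p300[ok, , drop = FALSE]),
                   anova = p300_anova, n = sum(ok)))
}

#' HEP analysis: prestimulus heartbeat-evoked potentials and detection
#'
#' Space x time cluster test (hits vs misses) on R-locked epochs in the
#' 250-400 ms post-R window over the EEG montage; electrodes of the
#' significant cluster (fallback C4/CP4/Cz when none, flagged) define the
#' per-trial HEP amplitude (mean over 296-400 ms), which is split into three
#' equal bins per subject for the tertile SDT analyses. Also: HEP amplitude
#' for hits/misses/correct rejections/resting beats with paired t tests,
#' heart-rate and HRV hit-vs-miss controls, and the SEP contrast between the
#' lowest and highest HEP tertile at C4.
#'
#' @inheritParams run_sep_analysis
#' @param fallback_channels electrode set used when no significant HEP
#'   cluster exists.
#' @return list report section.
#' @export
run_hep_analysis <- function(cohort, n_perm = 1000, seed = 2L,
                             fallback_channels = c("C4", "CP4", "Cz")) {
  prep <- as_prepared(cohort)
  stopifnot(prep[[1]]$full)
  times <- prep[[1]]$hep_times
  channels <- prep[[1]]$hep_channels
  widx <- which(times >= 0.25 & times < 0.4)
  wt <- times[widx]
  n_sub <- length(prep)
  hit_arr <- array(NA_real_, c(n_sub, length(channels), length(widx)))
  miss_arr <- hit_arr
  for (i in seq_len(n_sub)) {
    md <- prep[[i]]$hep_meta
    for (oc in c("hit", "miss")) {
      sel <- which(md$outcome %in% oc)
      if (length(sel) == 0L) next
      m <- apply(prep[[i]]$hep_trial[sel, , widx, drop = FALSE], c(2, 3), mean)
      if (oc == "hit") hit_arr[i, , ] <- m else miss_arr[i, , ] <- m
    }
  }
  mont <- prep[[1]]$montage
  nb <- build_neighbours(mont[mont$channel %in% channels, ])
  okhm <- stats::complete.cases(hit_arr[, 1, 1]) &
    stats::complete.cases(miss_arr[, 1, 1])
  cl <- paired_cluster_test(hit_arr[okhm, , , drop = FALSE],
                            miss_arr[okhm, , , drop = FALSE],
                            neighbours = nb, channels = channels, times = wt,
                            n_perm = n_perm, seed = derive_seed(seed, 1))
  elec <- cluster_channels(cl)
  used_fallback <- length(elec) == 0L
  if (used_fallback) {
    message("no significant HEP cluster: falling back to ",
            paste(fallback_channels, collapse = "/"))
    elec <- fallback_channels
  }
  eidx <- match(elec, channels)
  aidx <- which(times >= 0.296 & times < 0.4)

  # per-subject tertile SDT + condition-mean HEP amplitudes
  tert <- list(rate = NULL, dprime = NULL, criterion = NULL, loc_rate = NULL)
  amp_cond <- matrix(NA_real_, n_sub, 4,
                     dimnames = list(NULL, c("hit", "miss", "cr", "rest")))
  hr_hm <- matrix(NA_real_, n_sub, 2)
  hrv_hm <- matrix(NA_real_, n_sub, 2)
  sep_low <- NULL; sep_high <- NULL
  sep_times <- prep[[1]]$sep_times
  sidx <- which(sep_times >= 0 & sep_times < 0.6)
  for (i in seq_len(n_sub)) {
    p <- prep[[i]]
    amp <- apply(p$hep_trial[, eidx, aidx, drop = FALSE], 1, mean)
    md <- p$hep_meta
    for (oc in c("hit", "miss", "cr")) {
      sel <- md$outcome %in% oc
      if (any(sel)) amp_cond[i, oc] <- mean(amp[sel])
    }
    if (!is.null(p$hep_rest)) {
      amp_cond[i, "rest"] <- mean(p$hep_rest[, eidx, aidx])
    }
    md$hep_bin <- amplitude_bins(amp, 3L)
    s <- sdt_by_stratum(md, "hep_bin")
    if (nrow(s) == 3L && all(s$n_hit + s$n_miss >= 10)) {
      for (m in names(tert)) tert[[m]] <- rbind(tert[[m]], s[[m]])
    }
    # HR / HRV for hits vs misses among qualifying trials
    tr <- p$trials
    rr_of <- function(oc) {
      sel <- md$trial[md$outcome %in% oc]
      idx <- findInterval(tr$onset_s[match(sel, tr$trial)], p$r_peaks)
      diff(p$r_peaks)[pmin(idx, length(p$r_peaks) - 1L)]
    }
    rr_h <- rr_of("hit"); rr_m <- rr_of("miss")
    if (length(rr_h) > 2 && length(rr_m) > 2) {
      hr_hm[i, ] <- c(60 / mean(rr_h), 60 / mean(rr_m))
      hrv_hm[i, ] <- c(stats::sd(rr_h), stats::sd(rr_m)) * 1000
    }
    # SEP by HEP tertile (lowest vs highest), C4
    smeta <- p$sep_meta
    bin_of_trial <- md$hep_bin[match(smeta$trial, md$trial)]
    sep_low <- rbind(sep_low, cond_mean(p$sep_trial_c4[, sidx, drop = FALSE],
                                        bin_of_trial %in% 1L))
    sep_high <- rbind(sep_high, cond_mean(p$sep_trial_c4[, sidx, drop = FALSE],
                                          bin_of_trial %in% 3L))
  }
  within3 <- data.frame(hep_bin = c("low", "mid", "high"))
  tert_anova <- lapply(tert, function(m) {
    if (is.null(m) || nrow(m) < 6) return(NULL)
    rm_anova_gg(m, within3)
  })
  amp_tests <- rbind(
    paired_t_row("rest_vs_hit", amp_cond[, "rest"], amp_cond[, "hit"]),
    paired_t_row("rest_vs_miss", amp_cond[, "rest"], amp_cond[, "miss"]),
    paired_t_row("cr_vs_hit", amp_cond[, "cr"], amp_cond[, "hit"]),
    paired_t_row("cr_vs_miss", amp_cond[, "cr"], amp_cond[, "miss"]),
    paired_t_row("hit_vs_miss", amp_cond[, "hit"], amp_cond[, "miss"])
  )
  ok <- stats::complete.cases(hr_hm)
  hr_test <- paired_t_row("heart_rate_hit_vs_miss", hr_hm[ok, 1], hr_hm[ok, 2])
  hrv_test <- paired_t_row("hrv_hit_vs_miss", hrv_hm[ok, 1], hrv_hm[ok, 2])
  oks <- stats::complete.cases(sep_low) & stats::complete.cases(sep_high)
  cl_sep <- paired_cluster_test(sep_low[oks, , drop = FALSE],
                                sep_high[oks, , drop = FALSE],
                                times = sep_times[sidx], n_perm = n_perm,
                                seed = derive_seed(seed, 2))
  list(cluster_hit_vs_miss = cl,
       electrodes = elec, used_fallback = used_fallback,
       amplitude_by_condition = amp_cond, amplitude_tests = amp_tests,
       tertile_means = lapply(tert, function(m) if (is.null(m)) NULL else colMeans(m)),
       tertile_anova = tert_anova,
       hr_control = hr_test, hrv_control = hrv_test,
       cluster_sep_low_vs_high_hep = cl_sep)
}

#' Prestimulus alpha analysis
#'
#' Per-subject quintiles of the prestimulus sensorimotor alpha amplitude
#' with detection/localization-rate, criterion and sensitivity ANOVAs; a
#' monotonicity summary (Spearman rho of the quintile means); and additivity
#' ANOVAs: cardiac phase x alpha bin and HEP bin (low/high tertile) x alpha
#' bin on detection rate.
#'
#' @inheritParams run_sep_analysis
#' @param hep a [run_hep_analysis()] section (electrode set reused for the
#'   HEP x alpha ANOVA); when NULL the fallback electrodes are used.
#' @return list report section.
#' @export
run_alpha_analysis <- function(cohort, hep = NULL, seed = 3L) {
  prep <- as_prepared(cohort)
  stopifnot(prep[[1]]$full)
  n_sub <- length(prep)
  elec <- if (!is.null(hep)) hep$electrodes else c("C4", "CP4", "Cz")
  channels <- prep[[1]]$hep_channels
  times <- prep[[1]]$hep_times
  aidx <- which(times >= 0.296 & times < 0.4)
  eidx <- match(elec, channels)

  quint <- list(rate = NULL, dprime = NULL, criterion = NULL, loc_rate = NULL)
  pa_rate <- NULL     # phase x alpha detection rate, cells sys/dia x 5 bins
  ha_rate <- NULL     # hep(low/high) x alpha detection rate
  alpha_by_phase <- matrix(NA_real_, n_sub, 2)
  alpha_by_hep <- matrix(NA_real_, n_sub, 2)
  for (i in seq_len(n_sub)) {
    p <- prep[[i]]
    tr <- p$trials
    tr$alpha <- p$alpha_trial[match(tr$trial, p$sep_meta$trial)]
    tr <- tr[!is.na(tr$alpha), , drop = FALSE]
    tr$alpha_bin <- amplitude_bins(tr$alpha, 5L)
    s <- sdt_by_stratum(tr, "alpha_bin")
    if (nrow(s) == 5L && all(s$n_hit + s$n_miss >= 5)) {
      for (m in names(quint)) quint[[m]] <- rbind(quint[[m]], s[[m]])
    }
    # phase x alpha cells (stimulation trials; detection rate)
    cells <- expand.grid(phase = c("systole", "diastole"), bin = 1:5)
    r <- mapply(function(ph, b) {
      sel <- tr$stim & tr$phase == ph & tr$alpha_bin == b
      if (sum(sel) < 3) return(NA_real_)
      mean(tr$outcome[sel] == "hit")
    }, cells$phase, cells$bin)
    pa_rate <- rbind(pa_rate, r)
    alpha_by_phase[i, ] <- c(mean(tr$alpha[tr$stim & tr$phase == "systole"]),
                             mean(tr$alpha[tr$stim & tr$phase == "diastole"]))
    # HEP low/high x alpha (qualifying trials only)
    md <- p$hep_meta
    amp <- apply(p$hep_trial[, eidx, aidx, drop = FALSE], 1, mean)
    md$hep_bin <- amplitude_bins(amp, 3L)
    md$alpha <- tr$alpha[match(md$trial, tr$trial)]
    md <- md[!is.na(md$alpha) & md$hep_bin %in% c(1L, 3L), , drop = FALSE]
    md$alpha_bin <- amplitude_bins(md$alpha, 5L)
    cells2 <- expand.grid(hep = c(1L, 3L), bin = 1:5)
    r2 <- mapply(function(hb, b) {
      sel <- md$stim & md$hep_bin == hb & md$alpha_bin == b
      if (sum(sel) < 3) return(NA_real_)
      mean(md$outcome[sel] == "hit")
    }, cells2$hep, cells2$bin)
    ha_rate <- rbind(ha_rate, r2)
    alpha_by_hep[i, ] <- c(mean(md$alpha[md$hep_bin == 1L]),
                           mean(md$alpha[md$hep_bin == 3L]))
  }
  within5 <- data.frame(alpha_bin = paste0("q", 1:5))
  quint_anova <- lapply(quint, function(m) {
    if (is.null(m) || nrow(m) < 6) return(NULL)
    rm_anova_gg(m, within5)
  })
  rho <- if (!is.null(quint$rate)) {
    stats::cor(1:5, colMeans(quint$rate), method = "spearman")
  } else NA_real_
  wpa <- expand.grid(phase = c("sys", "dia"), alpha_bin = paste0("q", 1:5))
  ok <- stats::complete.cases(pa_rate)
  pa_anova <- rm_anova_gg(pa_rate[ok, , drop = FALSE], wpa)
  wha <- expand.grid(hep = c("low", "high"), alpha_bin = paste0("q", 1:5))
  ok2 <- stats::complete.cases(ha_rate)
  ha_anova <- rm_anova_gg(ha_rate[ok2, , drop = FALSE], wha)
  list(quintile_means = lapply(quint, function(m) if (is.null(m)) NULL else colMeans(m)),
       quintile_anova = quint_anova,
       rate_spearman_rho = rho,
       phase_x_alpha = list(anova = pa_anova, n = sum(ok),
                            alpha_comparable =
                              paired_t_row("alpha_sys_vs_dia",
                                           alpha_by_phase[, 1],
                                           alpha_by_phase[, 2])),
       hep_x_alpha = list(anova = ha_anova, n = sum(ok2),
                          alpha_comparable =
                            paired_t_row("alpha_lowhep_vs_highhep",
                                         alpha_by_hep[, 1],
                                         alpha_by_hep[, 2])),
       electrodes = elec)
}

#' Volume-conduction controls on the ECG channel
#'
#' (a) cluster test on the artifact-corrected ECG-channel waveforms for
#' systole vs diastole trials over 0-600 ms post-stimulus; (b) cluster test
#' on R-locked ECG segments 296-400 ms for hits vs misses. Neither should
#' produce significant clusters when EEG effects are genuinely cortical.
#'
#' @inheritParams run_sep_analysis
#' @return list with `residual_ecg_sys_vs_dia` and `ecg_hit_vs_miss`
#'   cluster results.
#' @export
run_controls <- function(cohort, n_perm = 1000, seed = 4L) {
  prep <- as_prepared(cohort)
  stopifnot(prep[[1]]$full, !is.null(prep[[1]]$sep_trial_ecg))
  times <- prep[[1]]$sep_times
  sidx <- which(times >= 0 & times < 0.6)
  sys <- t(vapply(prep, function(p) {
    cond_mean(p$sep_trial_ecg[, sidx, drop = FALSE],
              p$sep_meta$stim & p$sep_meta$phase == "systole")
  }, numeric(length(sidx))))
  dia <- t(vapply(prep, function(p) {
    cond_mean(p$sep_trial_ecg[, sidx, drop = FALSE],
              p$sep_meta$stim & p$sep_meta$phase == "diastole")
  }, numeric(length(sidx))))
  cl_a <- paired_cluster_test(sys, dia, times = times[sidx],
                              n_perm = n_perm, seed = derive_seed(seed, 1))
  htimes <- prep[[1]]$hep_times
  hidx <- which(htimes >= 0.296 & htimes < 0.4)
  hit <- t(vapply(prep, function(p) {
    cond_mean(p$ecg_hep_trial[, hidx, drop = FALSE],
              p$hep_meta$outcome %in% "hit")
  }, numeric(length(hidx))))
  miss <- t(vapply(prep, function(p) {
    cond_mean(p$ecg_hep_trial[, hidx, drop = FALSE],
              p$hep_meta$outcome %in% "miss")
  }, numeric(length(hidx))))
  ok <- stats::complete.cases(hit) & stats::complete.cases(miss)
  cl_b <- paired_cluster_test(hit[ok, , drop = FALSE], miss[ok, , drop = FALSE],
                              times = htimes[hidx], n_perm = n_perm,
                              seed = derive_seed(seed, 2))
  list(residual_ecg_sys_vs_dia = cl_a, ecg_hit_vs_miss = cl_b)
}

#' Run the complete group pipeline
#'
#' Prepares every subject once and assembles the phase, SEP, HEP, alpha and
#' control sections into a group report. With a fixed cohort and seed the
#' report is fully deterministic.
#'
#' @param cohort a [generate_cohort()] result (behaviour-only cohorts get
#'   the phase section only).
#' @param n_perm permutations per cluster test.
#' @param seed master seed for artifact triggers and permutations.
#' @return list of class `group_report`.
#' @export
run_group_pipeline <- function(cohort, n_perm = 1000, seed = NULL) {
  if (is.null(seed)) {
    seed <- if (inherits(cohort, "cohort")) cohort$config$seed else 1L
  }
  prep <- as_prepared(cohort, seed = seed)
  full <- prep[[1]]$full
  report <- list(phase = run_phase_analysis(prep))
  if (full) {
    report$sep <- run_sep_analysis(prep, n_perm = n_perm,
                                   seed = derive_seed(seed, 101))
    report$hep <- run_hep_analysis(prep, n_perm = n_perm,
                                   seed = derive_seed(seed, 102))
    report$alpha <- run_alpha_analysis(prep, hep = report$hep,
                                       seed = derive_seed(seed, 103))
    report$controls <- run_controls(prep, n_perm = n_perm,
                                    seed = derive_seed(seed, 104))
  }
  report$n_subjects <- length(prep)
  class(report) <- "group_report"
  report
}

#' @export
print.group_report <- function(x, ...) {
  cat("<group_report>", x$n_subjects, "subjects; sections:",
      paste(setdiff(names(x), "n_subjects"), collapse = ", "), "\n")
  invisible(x)
}
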