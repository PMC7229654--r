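# Signal-detection-theory scoring of detection/localization behaviour with
# uniform log-linear correction.

#' Label trial outcomes
#'
#' Hits and misses on stimulation trials, false alarms and correct rejections
#' on catch trials; correct/wrong localization on stimulation trials. Trials
#' with a missing detection response are flagged (`outcome = NA`) and
#' reported via a message; they are excluded from counts downstream.
#'
#' @param trials trial table with `stim`, `finger`, `response_yes`,
#'   `response_loc` columns.
#' @return the trial table with `outcome` (`hit`/`miss`/`fa`/`cr`) and
#'   `loc_correct` (logical, stimulation trials only) appended.
#' @export
classify_trials <- function(trials) {
  missing_resp <- is.na(trials$response_yes)
  if (any(missing_resp)) {
    message(sum(missing_resp), " trial(s) without detection response flagged")
  }
  outcome <- ifelse(trials$stim,
                    ifelse(trials$response_yes, "hit", "miss"),
                    ifelse(trials$response_yes, "fa", "cr"))
  outcome[missing_resp] <- NA_character_
  trials$outcome <- outcome
  trials$loc_correct <- ifelse(trials$stim & !missing_resp,
                               trials$response_loc == trials$finger, NA)
  trials
}

#' SDT measures with log-linear correction
#'
#' Corrected hit rate HR = (n_hit + 0.5) / (n_hit + n_miss + 1) and false
#' alarm rate FAR = (n_fa + 0.5) / (n_fa + n_cr + 1); the correction is
#' applied uniformly so extreme (0/100%) rates stay finite. Then
#' d' = z(HR) - z(FAR) and c = -(z(HR) + z(FAR)) / 2.
#'
#' @param n_hit,n_miss,n_fa,n_cr outcome counts.
#' @return list with corrected `hr`, `far`, `dprime`, `criterion` and the
#'   four counts.
#' @export
sdt_measures <- function(n_hit, n_miss, n_fa, n_cr) {
  n_stim <- n_hit + n_miss
  n_catch <- n_fa + n_cr
  if (n_stim <= 0 || n_catch <= 0) {
    stop("stimulation and catch totals must both be positive")
  }
  hr <- (n_hit + 0.5) / (n_stim + 1)
  far <- (n_fa + 0.5) / (n_catch + 1)
  zh <- qnorm(hr)
  zf <- qnorm(far)
  list(n_hit = n_hit, n_miss = n_miss, n_fa = n_fa, n_cr = n_cr,
       hr = hr, far = far,
       dprime = zh - zf, criterion = -(zh + zf) / 2)
}

#' Localization sensitivity from a two-alternative correct rate
#'
#' loc d' = sqrt(2) z(rate). The rate must already be strictly inside (0, 1);
#' raw 0/100% rates should first go through the log-linear corrected counts,
#' see [corrected_rate()].
#'
#' @param correct_rate correct-localization probability in (0, 1).
#' @return localization d'.
#' @export
localization_dprime <- function(correct_rate) {
  if (any(correct_rate <= 0 | correct_rate >= 1)) {
    stop("rate must be inside (0, 1); apply the log-linear correction to ",
         "the counts first (see corrected_rate())")
  }
  sqrt(2) * qnorm(correct_rate)
}

#' Log-linear corrected proportion
#'
#' (k + 0.5) / (n + 1): the same correction used for hit/false-alarm rates,
#' applied to any count pair (e.g. localization).
#'
#' @param k successes.
#' @param n total.
#' @return corrected proportion, strictly inside (0, 1).
#' @export
corrected_rate <- function(k, n) {
  stopifnot(all(n > 0), all(k >= 0 & k <= n))
  (k + 0.5) / (n + 1)
}

#' SDT measures within trial strata
#'
#' Computes [sdt_measures()] separately for each level of a stratifying
#' column (phase, delay bin, HEP bin, alpha bin, ...), using only in-stratum
#' stimulation and catch counts. Catch trials must carry the stratum label
#' too (they are phase-classified by their scheduled onset), which gives
#' stratum-specific false alarm rates.
#'
#' @param trials classified trial table (see [classify_trials()]).
#' @param stratum name of the stratifying column, or NULL for overall
#'   scoring.
#' @return data.frame with one row per stratum: counts, hr, far, dprime,
#'   criterion, detection rate (`rate`, raw hit proportion), localization
#'   rate and localization d' (log-linear corrected).
#' @export
sdt_by_stratum <- function(trials, stratum = NULL) {
  trials <- trials[!is.na(trials$outcome), , drop = FALSE]
  if (is.null(stratum)) {
    grp <- factor(rep("all", nrow(trials)))
  } else {
    grp <- factor(trials[[stratum]])
  }
  rows <- lapply(levels(grp), function(g) {
    tg <- trials[grp == g, , drop = FALSE]
    n_hit <- sum(tg$outcome == "hit")
    n_miss <- sum(tg$outcome == "miss")
    n_fa <- sum(tg$outcome == "fa")
    n_cr <- sum(tg$outcome == "cr")
    if (n_hit + n_miss == 0 || n_fa + n_cr == 0) {
      return(data.frame(stratum = g, n_hit = n_hit, n_miss = n_miss,
                        n_fa = n_fa, n_cr = n_cr, hr = NA, far = NA,
                        dprime = NA, criterion = NA, rate = NA,
                        loc_rate = NA, loc_dprime = NA))
    }
    m <- sdt_measures(n_hit, n_miss, n_fa, n_cr)
    n_loc <- sum(!is.na(tg$loc_correct))
    k_loc <- sum(tg$loc_correct, na.rm = TRUE)
    loc_rate <- if (n_loc > 0) k_loc / n_loc else NA_real_
    loc_dp <- if (n_loc > 0) localization_dprime(corrected_rate(k_loc, n_loc)) else NA_real_
    data.frame(stratum = g, n_hit = n_hit, n_miss = n_miss,
               n_fa = n_fa, n_cr = n_cr, hr = m$hr, far = m$far,
               dprime = m$dprime, criterion = m$criterion,
               rate = n_hit / (n_hit + n_miss),
               loc_rate = loc_rate, loc_dprime = loc_dp)
  })
  do.call(rbind, rows)
}
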