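# Circular cardiac phase: angle assignment, circular statistics, binary
# systole/diastole classification, delay bins.

#' Circular phase of an event within its cardiac cycle
#'
#' angle = 360 (onset - r_prev) / (r_next - r_prev), in degrees within
#' [0, 360); 0 marks the R-peak preceding the event. Vectorized.
#'
#' @param onset event time(s), seconds.
#' @param r_prev,r_next previous/subsequent R-peak times, seconds.
#' @return angle(s) in degrees.
#' @export
phase_angle <- function(onset, r_prev, r_next) {
  if (any(r_next <= r_prev)) stop("r_next must exceed r_prev")
  if (any(onset < r_prev | onset >= r_next)) {
    stop("onset must lie in [r_prev, r_next)")
  }
  360 * (onset - r_prev) / (r_next - r_prev)
}

#' Circular mean and resultant length
#'
#' @param angles angles in degrees.
#' @return list with `mean_angle` (degrees in [0, 360)) and `resultant`
#'   (mean resultant length, in [0, 1]).
#' @export
circular_mean <- function(angles) {
  if (length(angles) == 0L) stop("empty angle vector")
  rad <- angles * pi / 180
  cm <- mean(cos(rad))
  sm <- mean(sin(rad))
  r <- sqrt(cm^2 + sm^2)
  mu <- atan2(sm, cm) * 180 / pi
  list(mean_angle = (mu + 360) %% 360, resultant = r)
}

#' Rayleigh test for circular uniformity
#'
#' Z = n R^2 (R the mean resultant length); the p-value uses the standard
#' small-sample approximation
#' p = exp(sqrt(1 + 4n + 4(n^2 - (nR)^2)) - (1 + 2n)).
#'
#' Either supply raw angles, or `n` and `resultant` directly (the statistic
#' depends only on those).
#'
#' @param angles angles in degrees (optional if `n`/`resultant` given).
#' @param n sample size.
#' @param resultant mean resultant length in [0, 1].
#' @return list of class `circular_summary`: `n`, `mean_angle` (NA when only
#'   `n`/`resultant` supplied), `resultant`, `rayleigh_z`, `rayleigh_p`.
#' @export
rayleigh_test <- function(angles = NULL, n = NULL, resultant = NULL) {
  mean_angle <- NA_real_
  if (!is.null(angles)) {
    cm <- circular_mean(angles)
    n <- length(angles)
    resultant <- cm$resultant
    mean_angle <- cm$mean_angle
  }
  if (is.null(n) || is.null(resultant)) stop("supply angles, or n and resultant")
  if (n < 4) stop("Rayleigh test needs n >= 4")
  z <- n * resultant^2
  rn <- n * resultant
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - rn^2)) - (1 + 2 * n))
  p <- min(p, 1)
  structure(list(n = n, mean_angle = mean_angle, resultant = resultant,
                 rayleigh_z = z, rayleigh_p = p),
            class = "circular_summary")
}

#' Classify an event as systole / diastole / neither
#'
#' Looks up the cycle containing the onset and applies the half-open systole
#' window [R, t_end) and the equal-length diastole window ending at the next
#' R-peak. Events in flagged cycles, or not covered by any complete cycle,
#' return `"invalid_cycle"`. Vectorized over onsets.
#'
#' @param onset event time(s), seconds.
#' @param cycles a [build_cycle_table()] result.
#' @return character vector of labels: `"systole"`, `"diastole"`,
#'   `"neither"`, `"invalid_cycle"`.
#' @export
classify_phase <- function(onset, cycles) {
  idx <- findInterval(onset, cycles$r_onset_s)
  out <- rep("invalid_cycle", length(onset))
  ok <- idx >= 1L & idx <= nrow(cycles)
  ok[ok] <- onset[ok] < cycles$r_next_s[idx[ok]]
  ok[ok] <- ok[ok] & cycles$valid[idx[ok]]
  i <- idx[ok]
  on <- onset[ok]
  lab <- ifelse(on >= cycles$sys_start_s[i] & on < cycles$sys_end_s[i], "systole",
                ifelse(on >= cycles$dia_start_s[i] & on < cycles$dia_end_s[i],
                       "diastole", "neither"))
  out[ok] <- lab
  out
}

#' Delay bin relative to the previous R-peak
#'
#' Half-open 200-ms bins: [0,200), [200,400), [400,600), [600,800) ms;
#' anything else is `"out_of_range"`. Vectorized.
#'
#' @param onset event time(s), seconds.
#' @param r_prev previous R-peak time(s), seconds.
#' @return factor with levels `0-200`, `200-400`, `400-600`, `600-800`,
#'   `out_of_range`.
#' @export
delay_bin <- function(onset, r_prev) {
  if (any(onset < r_prev)) stop("onset must not precede r_prev")
  d_ms <- (onset - r_prev) * 1000
  lev <- c("0-200", "200-400", "400-600", "600-800", "out_of_range")
  lab <- ifelse(d_ms < 200, lev[1],
                ifelse(d_ms < 400, lev[2],
                       ifelse(d_ms < 600, lev[3],
                              ifelse(d_ms < 800, lev[4], lev[5]))))
  factor(lab, levels = lev)
}

#' Annotate a trial table with cardiac phase information
#'
#' Adds, per trial: circular `angle` (degrees; NA if the onset is not inside
#' a complete cycle), `phase` label, `delay_s` from the previous R-peak, and
#' the `delay_bin` factor.
#'
#' @param trials trial table with an `onset_s` column.
#' @param cycles a [build_cycle_table()] result.
#' @return the trial table with the four columns appended.
#' @export
annotate_phase <- function(trials, cycles) {
  idx <- findInterval(trials$onset_s, cycles$r_onset_s)
  inside <- idx >= 1L & idx <= nrow(cycles)
  inside[inside] <- trials$onset_s[inside] < cycles$r_next_s[idx[inside]]
  angle <- rep(NA_real_, nrow(trials))
  delay <- rep(NA_real_, nrow(trials))
  angle[inside] <- phase_angle(trials$onset_s[inside],
                               cycles$r_onset_s[idx[inside]],
                               cycles$r_next_s[idx[inside]])
  delay[inside] <- trials$onset_s[inside] - cycles$r_onset_s[idx[inside]]
  trials$angle <- angle
  trials$phase <- classify_phase(trials$onset_s, cycles)
  trials$delay_s <- delay
  trials$delay_bin <- factor(rep("out_of_range", nrow(trials)),
                             levels = levels(delay_bin(0, 0)))
  trials$delay_bin[inside] <- delay_bin(trials$onset_s[inside],
                                        cycles$r_onset_s[idx[inside]])
  trials
}

#' @export
print.circular_summary <- function(x, ...) {
  cat(sprintf("Rayleigh test: n = %d, R = %.3f, Z = %.3f, p = %.4g\n",
              x$n, x$resultant, x$rayleigh_z, x$rayleigh_p))
  invisible(x)
}
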