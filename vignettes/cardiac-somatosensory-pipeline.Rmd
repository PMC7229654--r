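---
title: "Methods: cardiac modulation of somatosensory detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cardiac modulation of somatosensory detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the methods implemented in `cardioperc`: the
generative model behind the synthetic cohorts, the analysis conventions the
package commits to, and the design decisions and limitations a user should
know about. It states no empirical results; all quantitative claims about
the package are made (and checked) by the test suite and by
`scripts/acceptance.R`.

# 1. The scientific question

The pipeline is built to test two dissociations in near-threshold
somatosensory detection, framed in equal-variance signal detection theory
(SDT):

* **Cardiac phase acts on sensitivity.** Detection d′ is lower for stimuli
  presented during systole than during diastole, while the decision
  criterion c does not differ between phases.
* **The heartbeat-evoked potential (HEP) acts on the criterion.** A larger
  prestimulus HEP (the cortical response 250–400 ms after the R-peak)
  predicts a more conservative criterion, with no change in d′.

A third predictor, prestimulus sensorimotor alpha amplitude, also shifts
the criterion; the model treats the cardiac and cortical criterion shifts
as additive (no phase × alpha interaction).

# 2. Generative model

`generate_subject()` draws, in order:

1. **Cardiac timing.** RR intervals are truncated-normal
   (`mean_rr` = 0.80 s, `sdnn` = 0.05 s, truncated to [0.4, 1.2] s);
   per-cycle systole lengths are truncated-normal (333 ± 21 ms, capped at
   49% of the RR interval). The ECG trace is a piecewise PQRST template
   per beat (unit R amplitude) plus white noise `ecg_noise_sd`. The true
   R-peak times and true t-wave ends are recorded in `$truth`.
2. **Trial schedule.** 8 blocks × (100 stimulation + 20 catch) trials.
   Onsets sit in jittered slots of mean spacing `mean_iti` = 2.4 s, which
   makes stimulus onsets uniform over the cardiac cycle (the test suite
   checks this with the Rayleigh test). A trailing stimulation-free rest
   segment of `rest_duration` = 180 s closes the recording.
3. **Latents.** Per-beat HEP amplitude latents h ~ N(0,1) and per-trial
   alpha latents a ~ N(0,1).
4. **Behaviour.** Each stimulation trial gets a true phase label from its
   onset (systole/diastole windows, Section 3); the internal evidence is
   X ~ N(d′(phase)/2, 1) for stimulation trials and N(−d′/2, 1) on catch
   trials, compared against c = `criterion_base` + `beta_hep`·h +
   `beta_alpha`·a. Localization (left/right of two fingers) is correct
   with probability 0.889 on hits and 0.570 on misses.
5. **EEG** (in `signals = "full"` mode). Eleven channels (ten EEG + ECG):
   1/f background noise (`noise_sd`), sensorimotor alpha at C4 whose
   envelope follows the alpha latent, a cardiac field artifact (CFA) —
   the ECG template volume-conducted into the EEG channels with a
   spatial gradient (`cfa_amp` at the strongest channel, O2 isolated) —
   an HEP deflection after each R-peak scaled by the beat's latent h, and
   SEP components on stimulation trials (P50, N140, P300) whose
   amplitudes are attenuated by `sep_hep_slope` per SD of h and whose
   P300 is gained up on detected and diastole trials.

Everything injected is also recorded: `$truth` holds the per-trial phase,
delay from the previous R-peak, latents, evidence, and the per-beat timing
ground truth, so every analysis stage can be validated against a known
answer.

`signals = "behavior"` skips steps 1's waveform rendering and step 5
entirely (timing, latents, and responses are still generated), and runs
two orders of magnitude faster; it is the mode used for Monte Carlo
calibration of the statistics.

## Key parameters

| Parameter | Default | Role |
|---|---|---|
| `mean_rr`, `sdnn` | 0.80 s, 0.05 s | RR-interval distribution |
| `systole_mean`, `systole_sd` | 333 ms, 21 ms | electrical systole length |
| `dprime_systole`, `dprime_diastole` | 1.48, 1.59 | phase effect on sensitivity |
| `criterion_base` | 0.76 | baseline criterion |
| `beta_hep`, `beta_alpha` | 0.12, 0.10 | criterion shift per SD of latent |
| `loc_correct_hit`, `loc_correct_miss` | 0.889, 0.570 | localization accuracy |
| `mean_iti` | 2.4 s | trial spacing (phase-uniform onsets) |
| `rest_duration` | 180 s | stimulation-free tail (see Section 6) |
| `noise_sd`, `cfa_amp` | 6 µV, 5 µV | EEG noise and artifact scale |
| `sep_hep_slope` | 0.15 | SEP attenuation per SD of HEP latent |

The behavioural values are chosen so that the intended dissociations are
present at realistic effect sizes rather than being trivially large; the
consequences for statistical power are discussed in Section 6.

# 3. Analysis conventions

These conventions are fixed package-wide; tests pin each one.

* **Half-open windows everywhere.** A window [a, b) includes a and
  excludes b — epochs, component windows, delay bins (0–200 ms is
  `[0, 0.2)`), and the systole window itself. Sample indices are obtained
  by flooring (`floor(t * fs)`), never rounding.
* **Cardiac phase.** Systole is `[R, t_end)` where t_end is the t-wave
  end; diastole is the window of the *same length* ending at the next
  R-peak. The stretch in between belongs to neither phase and such trials
  are excluded from binary-phase contrasts. The phase *angle* is
  360° · (onset − R) / RR.
* **T-wave end (trapezium method).** The t-peak is the maximum in
  `[R + 150 ms, R + min(500 ms, 0.6·RR)]`; the t-end is the point on the
  descending limb maximizing the trapezium area
  A = ½(y_peak − y_m)(2·x_lim − x_m − x_peak) with x_lim 200 ms after the
  t-peak (clipped to the cycle).
* **Cycle validity.** A single pass flags cycles whose RR deviates more
  than 4 SD from the recording mean; flagged cycles are excluded from
  phase assignment and HRV.
* **SDT with the log-linear correction.** Rates are (k + 0.5)/(n + 1);
  d′ = z(HR) − z(FAR), c = −(z(HR) + z(FAR))/2; localization
  d′ = √2 · z(corrected proportion correct). Stratified scoring
  (`sdt_by_stratum`) uses the stratum's *own* false-alarm rate (catch
  trials also carry a phase).
* **Rayleigh test.** The small-sample approximation
  p = exp(√(1 + 4n + 4(n² − (nR)²)) − (1 + 2n)) is used throughout.
* **Morlet wavelets.** Cycles grow linearly from 4 at 5 Hz to 10 at
  40 Hz; the wavelet is normalized so a unit-amplitude sinusoid at the
  centre frequency returns modulus 1. Samples whose wavelet support
  crosses the data edge are flagged, and prestimulus windows that touch
  flagged samples are an error, not a silent NA.
* **Cluster permutation test.** Pointwise paired t; threshold
  |t| > t₀.₉₇₅ at n−1 df; clusters are sign-consistent connected
  components under temporal adjacency (and spatial neighbourhood for
  space × time data); mass is the sum of t values; the null is the
  maximum |mass| over random sign flips; p = (1 + #exceedances)/(1 +
  n_perm). Constant-zero differences give t = 0 by convention.
* **Repeated-measures ANOVA.** Fit via `car::Anova` on a multivariate
  linear model; the Greenhouse–Geisser correction is applied whenever a
  within factor has more than two levels. A textbook epsilon formula
  (orthonormal contrasts) serves as the oracle in the tests.
* **Equal-count amplitude bins.** n observations into k bins by sorted
  order, remainders going to the *lower* bins first, ties broken by
  original position (stable).
* **Artifact correction.** The CFA template is the phase-conditional mean
  of epochs around *random triggers* placed in stimulation-free cardiac
  cycles; correction subtracts the template matched to each epoch's
  cardiac delay. Because the template is a conditional mean, cancellation
  is a property of condition averages, not of single epochs.
* **Seeds.** Every stochastic routine takes an explicit seed; cohort
  member seeds are derived deterministically from the master seed, so a
  `cohort_config(seed = s)` cohort is fully reproducible.

# 4. The group pipeline

`run_group_pipeline()` applies, per subject, the full chain (R-peaks →
t-wave ends → cycle table → phase annotation → SDT; plus, in full mode,
filtering, artifact correction, SEP/HEP epoching and prestimulus alpha),
then runs the group statistics:

* phase analysis — per-phase SDT, six paired t tests, delay-bin ANOVAs
  with adjacent post-hoc tests, per-subject and group circular uniformity,
  and heart-rate/HRV correlations with the phase effect;
* SEP analysis — systole-vs-diastole and hit-vs-miss cluster tests at C4
  and a detection × phase ANOVA on the P300 window;
* HEP analysis — a space × time hit-vs-miss cluster test, tertile SDT
  ANOVAs on single-trial HEP amplitude, comparisons against correct
  rejections and resting heartbeats, heart-rate controls, and the
  SEP-by-HEP-tertile contrast;
* alpha analysis — quintile SDT ANOVAs and the phase × alpha and
  HEP × alpha interaction tests;
* controls — the same contrasts run on the *corrected ECG channel*, which
  must be null if artifact correction worked.

Subjects whose stimulus onsets are non-uniform over the cardiac cycle
(subject-level Rayleigh p < 0.05) are excluded from phase statistics.

# 5. Design decisions

* **In-memory lists + delimited text instead of binary containers.**
  Datasets are plain R lists; tabular results (trial tables, cycle
  tables, reports) export to TSV/JSON. This keeps the package free of
  binary-format dependencies and makes every artifact diffable and
  testable; users with existing recordings adapt them by constructing the
  same lists (`matrix` of channels × samples, a trial data.frame, fs).
* **Library, not a shell tool.** The public functions compose in a few
  lines (see the README); a thin script (`scripts/acceptance.R`) shows
  the batch pattern.
* **Buy standard numerics, build the methods.** Filtering comes from
  `signal`, ANOVA machinery from `car`, tests and distributions from
  `stats`. The domain-specific methods — trapezium t-wave end,
  equal-length phase windows, small-sample Rayleigh p, log-linear SDT,
  random-trigger artifact subtraction, the Morlet convention, the cluster
  permutation engine, and the generator — are implemented here, because
  their exact conventions *are* the contribution being tested.

# 6. Limitations

* **Artifact-template cycle-selection bias.** Random triggers must come
  from stimulation-free cycles. If the rest segment is short, most such
  cycles are the ones squeezed between trials, which are biased toward
  short RR intervals; the resulting template mismatch leaves a
  phase-dependent residual that can contaminate the ECG-channel control.
  The generator therefore defaults to a long rest segment (180 s), and
  real-data users should supply a dedicated resting recording for
  template estimation.
* **Power of the phase → d′ contrast.** At the default effect
  (d′ 1.48 vs 1.59) the per-subject, per-phase d′ estimate is dominated
  by false-alarm-rate noise from ~65 catch trials per phase, so the
  paired t test at n = 37 is underpowered relative to conventional
  targets. This is a property of the design (catch-trial count), not of
  the implementation; the acceptance tests report it honestly rather
  than inflating the injected effect.
* **Per-epoch artifact residuals.** Template subtraction cancels the CFA
  in condition averages; single corrected epochs retain their
  delay-specific deviation from the conditional mean. Single-trial
  analyses of channels with strong CFA should not assume per-epoch
  cleanliness.
* **The "neither" gap.** Because diastole is defined as an equal-length
  window before the next R-peak, a portion of each cycle belongs to
  neither phase and those trials drop out of binary contrasts. Analyses
  needing full coverage should use the continuous phase angle or delay
  bins instead.
* **Schematic physiology.** The ECG template, CFA topography, and 1/f
  EEG noise are deliberately simple; the generator is a test harness for
  the analysis code, not a biophysical simulator.
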