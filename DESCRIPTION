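Package: cardioperc
Title: Cardiac-Cycle and Heartbeat-Evoked Modulation of Somatosensory Perception
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for studying how the cardiac cycle and
    heartbeat-evoked potentials (HEPs) modulate somatosensory detection and
    evoked potentials. Parses ECG into R-peaks, trapezoid-algorithm t-wave
    ends and equal-length systole/diastole windows; assigns circular cardiac
    phase to stimuli and provides Rayleigh statistics; scores yes/no
    detection behaviour under equal-variance signal detection theory with
    log-linear correction; extracts somatosensory- and heartbeat-evoked
    potentials with random-trigger cardiac-artifact subtraction; computes
    Morlet time-frequency prestimulus alpha; runs nonparametric cluster-based
    permutation tests over time and space-time; and orchestrates the full
    group analysis. A synthetic cohort generator with recorded ground truth
    (coupled ECG, EEG and behaviour) makes every stage verifiable without
    human recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    signal,
    car,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
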