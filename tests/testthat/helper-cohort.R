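# Shared, lazily-built fixtures reused across test files (one build per
# test run).

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures, inherits = FALSE)) {
    assign(name, expr, envir = .fixtures)
  }
  get(name, envir = .fixtures, inherits = FALSE)
}

# small full-signal cohort: 8 subjects, 3 blocks (360 trials each)
small_full_cohort <- function() {
  fixture("small_full",
          generate_cohort(cohort_config(n_subjects = 8, n_blocks = 3,
                                        seed = 11)))
}

# the same cohort run through per-subject preparation
small_prepared <- function() {
  fixture("small_prep",
          suppressMessages(prepare_cohort(small_full_cohort(), seed = 11)))
}

# one full-signal subject at the default design (960 trials)
full_subject <- function() {
  fixture("full_subject",
          generate_subject(cohort_config(n_subjects = 1, seed = 5), 501))
}

behavior_cohort <- function(n_subjects = 37, seed = 1, ...) {
  generate_cohort(cohort_config(n_subjects = n_subjects,
                                signals = "behavior", seed = seed, ...))
}
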