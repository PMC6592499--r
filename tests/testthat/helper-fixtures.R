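# Shared fixtures, built once per test run and memoised across files.

.fixtures <- new.env(parent = emptyenv())

memo_fixture <- function(key, fn) {
  if (is.null(.fixtures[[key]])) assign(key, fn(), envir = .fixtures)
  get(key, envir = .fixtures)
}

# a small, fast cohort for unit tests
small_cohort <- function() memo_fixture("small_cohort", function()
  generate_cohort(n_patients = 6, duration = 300, seed = 42))

small_windows <- function() memo_fixture("small_windows", function()
  preprocess_cohort(small_cohort()))

small_features <- function() memo_fixture("small_features", function()
  window_features(small_windows()))

# the frozen study-scale cohort: 75 patients, paired 900-s recordings
FROZEN_SEED <- 1

frozen_cohort <- function() memo_fixture("frozen_cohort", function()
  generate_cohort(n_patients = 75, duration = 900, seed = FROZEN_SEED))

frozen_dataset <- function() memo_fixture("frozen_dataset", function()
  build_af_dataset(frozen_cohort()))

# brute-force re-statement of the PAC rule, kept deliberately naive so it
# is an independent oracle for detect_pacs()
brute_force_pac_flags <- function(intervals, threshold = 0.85) {
  m <- sum(intervals) / length(intervals)
  flags <- logical(length(intervals) + 1)
  for (i in seq_along(intervals)) {
    if (intervals[i] < threshold * m) flags[i + 1] <- TRUE
  }
  flags
}

# trapezoidal area under an empirical ROC, the dual computation of the
# midrank Mann-Whitney AUC
trapezoid_auc <- function(scores, labels) {
  rc <- roc_curve(scores, labels)
  sum(diff(rc$fpr) * (head(rc$tpr, -1) + tail(rc$tpr, -1)) / 2)
}
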