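test_that("parameter validation names the offending field", {
  expect_error(rhythm_params("SR", mean_rr = -1), "mean_rr",
               class = "ppgaf_parameter_error")
  expect_error(rhythm_params("SR", coupling_frac = 0.9),
               "coupling_frac", class = "ppgaf_parameter_error")
  expect_error(rhythm_params("SR", compensatory_frac = 0.8),
               "compensatory_frac", class = "ppgaf_parameter_error")
  expect_error(rhythm_params("SR", fs = 10), "fs",
               class = "ppgaf_parameter_error")
  expect_error(rhythm_params("SR", duration = 0), "duration",
               class = "ppgaf_parameter_error")
})

test_that("zero-variance sinus rhythm gives exactly constant intervals", {
  p <- rhythm_params("SR", mean_rr = 1, rr_sd = 0, resp_mod_depth = 0,
                     duration = 120)
  rr <- simulate_rr(p)
  expect_true(all(rr$intervals == 1))
  expect_false(any(rr$pac_flags))
})

test_that("AF intervals reproduce the configured spread and lack serial structure", {
  set.seed(11)
  p <- rhythm_params("AF", mean_rr = 0.8, rr_sd = 0.24 * 0.8, duration = 600)
  rr <- simulate_rr(p)
  iv <- rr$intervals
  expect_gt(length(iv), 500)
  cv <- sd(iv) / mean(iv)
  expect_gt(cv, 0.8 * 0.24)
  expect_lt(cv, 1.2 * 0.24)
  r1 <- cor(iv[-1], iv[-length(iv)])
  expect_lt(abs(r1), 0.1)
  expect_true(all(iv > 0.25))
})

test_that("interval count tracks duration / mean RR", {
  set.seed(2)
  p <- rhythm_params("SR", mean_rr = 1, duration = 900)
  rr <- simulate_rr(p)
  expect_gt(length(rr$intervals), 900 * 0.95)
  expect_lt(length(rr$intervals), 900 * 1.05)
  expect_gte(sum(rr$intervals), 900)
})

test_that("PAC insertion is an identity at rate zero and errors on AF", {
  p <- rhythm_params("SR", mean_rr = 1, duration = 60, pac_rate = 0)
  rr <- simulate_rr(p)
  expect_identical(insert_pacs(rr, p), rr)
  p_af <- rhythm_params("AF", duration = 60)
  p_af$pac_rate <- 2
  rr_af <- simulate_rr(p_af)
  expect_error(insert_pacs(rr_af, p_af), "pac_rate",
               class = "ppgaf_parameter_error")
})

test_that("inserted PACs have the configured coupling interval by construction", {
  set.seed(4)
  p <- rhythm_params("SR", mean_rr = 1, rr_sd = 0, resp_mod_depth = 0,
                     duration = 300, pac_rate = 4, coupling_frac = 0.6)
  rr <- insert_pacs(simulate_rr(p), p)
  expect_gt(sum(rr$pac_flags), 0)
  pac_idx <- which(rr$pac_flags)
  expect_true(all(pac_idx > 1))
  # preceding interval of every inserted beat is 0.6 x the (constant) RR
  expect_equal(rr$intervals[pac_idx - 1], rep(0.6, length(pac_idx)),
               tolerance = 1e-12)
  # and the compensatory pause is never itself premature
  expect_true(all(rr$intervals[pac_idx] >= 1))
})

test_that("realised PAC count follows the configured Poisson rate", {
  set.seed(8)
  p <- rhythm_params("SR", mean_rr = 1, duration = 900, pac_rate = 6)
  rr <- insert_pacs(simulate_rr(p), p)
  n <- sum(rr$pac_flags)
  expect_gt(n, 90 - 3 * sqrt(90))
  expect_lt(n, 90 + 3 * sqrt(90))
  # total duration preserved to within about one interval
  expect_lt(abs(max(rr$beat_times) - 903), 1.5)
})

test_that("every inserted PAC violates the 85% rule within its window", {
  set.seed(15)
  p <- rhythm_params("SR", mean_rr = 0.9, duration = 300, pac_rate = 8)
  rr <- insert_pacs(simulate_rr(p), p)
  pr <- detect_pacs(rr)
  expect_true(all(pr$flags[rr$pac_flags]))
})

test_that("noise-free constant-rate rendering is periodic at the beat period", {
  p <- rhythm_params("SR", mean_rr = 1, rr_sd = 0, resp_mod_depth = 0,
                     noise_sd = 0, duration = 30)
  rec <- render_ppg(simulate_rr(p), p)
  x <- rec$samples
  per <- round(p$fs * 1)
  core <- 500:2500
  expect_lt(max(abs(x[core] - x[core + per])), 1e-4)
})

test_that("clean renders show one prominent peak per beat", {
  p <- rhythm_params("SR", mean_rr = 0.9, rr_sd = 0.02, noise_sd = 0,
                     duration = 60)
  set.seed(3)
  rr <- simulate_rr(p)
  rec <- render_ppg(rr, p)
  x <- rec$samples
  pk <- which(diff(sign(diff(x))) < 0) + 1
  n_prom <- sum(x[pk] > 0.5 * max(x))
  expect_lt(abs(n_prom - length(rec$beat_times)), 3)
})

test_that("waveform noise is additive: doubling noise_sd doubles the residual", {
  p0 <- rhythm_params("SR", mean_rr = 1, rr_sd = 0, resp_mod_depth = 0,
                      noise_sd = 0, duration = 60)
  rr <- simulate_rr(p0)
  clean <- render_ppg(rr, p0)$samples
  p1 <- p0; p1$noise_sd <- 0.05
  p2 <- p0; p2$noise_sd <- 0.10
  set.seed(5); r1 <- sd(render_ppg(rr, p1)$samples - clean)
  set.seed(5); r2 <- sd(render_ppg(rr, p2)$samples - clean)
  expect_equal(r2 / r1, 2, tolerance = 1e-9)
  expect_equal(r1, 0.05, tolerance = 0.05)
})

test_that("rendering rejects a sampling rate too low for the pulse template", {
  p <- rhythm_params("SR", duration = 30)
  rr <- simulate_rr(p)
  p$fs <- 15
  expect_error(render_ppg(rr, p), "fs", class = "ppgaf_parameter_error")
})

test_that("a cohort yields one AF and one SR recording per patient", {
  coh <- small_cohort()
  expect_length(coh$records, 12)
  expect_equal(sum(vapply(coh$records, function(r) r$label, "") == "AF"), 6)
  for (i in seq_len(6)) {
    pair <- coh$records[c(2 * i - 1, 2 * i)]
    expect_equal(pair[[1]]$patient_id, pair[[2]]$patient_id)
    expect_identical(pair[[1]]$phase, "pre_dcc")
    expect_identical(pair[[2]]$phase, "post_dcc")
  }
})

test_that("identical seeds give bit-identical cohorts", {
  c1 <- generate_cohort(n_patients = 3, duration = 60, seed = 77)
  c2 <- generate_cohort(n_patients = 3, duration = 60, seed = 77)
  expect_identical(c1, c2)
})

test_that("about 30% of post-cardioversion windows carry PACs in the frozen cohort", {
  prev <- cohort_pac_window_prevalence(frozen_cohort())
  expect_gt(prev, 0.298 - 0.05)
  expect_lt(prev, 0.298 + 0.05)
})

test_that("records round-trip through the text + JSON sidecar format", {
  coh <- generate_cohort(n_patients = 1, duration = 30, seed = 5)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  back <- read_cohort(dir)
  expect_equal(back$records[[1]]$samples, coh$records[[1]]$samples,
               tolerance = 1e-6)
  expect_identical(back$records[[2]]$pac_flags, coh$records[[2]]$pac_flags)
  expect_equal(back$records[[2]]$beat_times, coh$records[[2]]$beat_times,
               tolerance = 1e-9)
  expect_identical(back$records[[1]]$label, "AF")
  expect_equal(back$patients$pac_rate, coh$patients$pac_rate)
})
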