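#' Rhythm generator parameters
#'
#' Bundles the parameters that drive one synthetic recording: rhythm class,
#' inter-beat-interval (RR) statistics, PAC insertion behaviour for sinus
#' rhythm, respiratory modulation, waveform noise, sampling rate and
#' duration.
#'
#' @param rhythm `"AF"` (atrial fibrillation) or `"SR"` (sinus rhythm).
#' @param mean_rr Mean RR interval in seconds. Must be positive.
#' @param rr_sd RR variability in seconds. For AF this sets the spread of
#'   the interval distribution (the coefficient of variation
#'   `rr_sd / mean_rr` must be at least 0.15, reflecting the irregularly
#'   irregular rhythm); for SR it is the beat-to-beat jitter on top of
#'   respiratory modulation.
#' @param pac_rate Expected PACs per minute (SR only; ignored for AF where
#'   it must be 0).
#' @param coupling_frac PAC prematurity as a fraction of the local mean RR:
#'   either a single value or a range `c(lo, hi)` sampled uniformly per
#'   PAC. All values must lie strictly inside (0, 0.85) so that every
#'   inserted PAC is detectable by the 85\% rule.
#' @param compensatory_frac Post-PAC pause as a fraction of the local mean
#'   RR; must be at least 1 so the pause is never itself premature.
#' @param resp_mod_depth Fractional depth of sinusoidal respiratory RR
#'   modulation (SR only).
#' @param resp_rate Respiratory rate in Hz.
#' @param noise_sd Standard deviation of additive Gaussian waveform noise,
#'   in units of the nominal pulse amplitude (1).
#' @param amp_slope Pulse-amplitude modulation per unit relative change of
#'   the preceding RR interval (shorter interval, smaller pulse).
#' @param fs Sampling rate in Hz; at least 20 so the pulse template is
#'   representable.
#' @param duration Recording duration in seconds.
#' @param seed Optional integer seed applied before simulation; `NULL`
#'   (default) uses the current RNG stream.
#'
#' @return An object of class `rhythm_params` (a validated list).
#' @seealso [simulate_rr()], [insert_pacs()], [render_ppg()]
#' @export
#' @examples
#' p <- rhythm_params("SR", mean_rr = 1, rr_sd = 0.02, pac_rate = 3,
#'                    duration = 120)
#' rr <- simulate_rr(p)
rhythm_params <- function(rhythm = c("SR", "AF"),
                          mean_rr = if (rhythm == "AF") 0.65 else 0.9,
                          rr_sd = if (rhythm == "AF") 0.25 * mean_rr else 0.025,
                          pac_rate = 0,
                          coupling_frac = c(0.55, 0.80),
                          compensatory_frac = 1.3,
                          resp_mod_depth = 0.03,
                          resp_rate = 0.25,
                          noise_sd = 0.05,
                          amp_slope = 0.5,
                          fs = 100,
                          duration = 900,
                          seed = NULL) {
  rhythm <- match.arg(rhythm)
  check_number(mean_rr, "mean_rr", lower = 0, strict_lower = TRUE)
  check_number(rr_sd, "rr_sd", lower = 0)
  check_number(pac_rate, "pac_rate", lower = 0)
  if (!is.numeric(coupling_frac) || !length(coupling_frac) %in% 1:2 ||
      any(coupling_frac <= 0) || any(coupling_frac >= 0.85))
    stop_ppgaf("'coupling_frac' must lie strictly within (0, 0.85)",
               "ppgaf_parameter_error")
  if (length(coupling_frac) == 2 && coupling_frac[1] > coupling_frac[2])
    stop_ppgaf("'coupling_frac' range must be increasing",
               "ppgaf_parameter_error")
  check_number(compensatory_frac, "compensatory_frac", lower = 1)
  check_number(resp_mod_depth, "resp_mod_depth", lower = 0, upper = 0.5)
  check_number(resp_rate, "resp_rate", lower = 0)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(amp_slope, "amp_slope", lower = 0)
  check_number(fs, "fs", lower = 20)
  check_number(duration, "duration", lower = 0, strict_lower = TRUE)
  if (!is.null(seed)) check_number(seed, "seed")
  structure(
    list(rhythm = rhythm, mean_rr = mean_rr, rr_sd = rr_sd,
         pac_rate = pac_rate, coupling_frac = coupling_frac,
         compensatory_frac = compensatory_frac,
         resp_mod_depth = resp_mod_depth, resp_rate = resp_rate,
         noise_sd = noise_sd, amp_slope = amp_slope, fs = fs,
         duration = duration, seed = seed),
    class = "rhythm_params"
  )
}

new_rr_series <- function(beat_times, pac_flags = NULL, rhythm = NA_character_) {
  n <- length(beat_times)
  if (is.null(pac_flags)) pac_flags <- rep(FALSE, n)
  stopifnot(length(pac_flags) == n)
  structure(
    list(beat_times = beat_times,
         intervals = diff(beat_times),
         pac_flags = pac_flags,
         rhythm = rhythm),
    class = "rr_series"
  )
}

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf("<rr_series> %d beats over %.1f s (%s)%s\n",
              length(x$beat_times), max(x$beat_times) - min(x$beat_times),
              if (is.na(x$rhythm)) "unlabelled" else x$rhythm,
              if (any(x$pac_flags)) sprintf(", %d PACs", sum(x$pac_flags)) else ""))
  invisible(x)
}

# minimum physiological interval enforced throughout the generator (s)
.RR_FLOOR <- 0.26

#' Simulate an inter-beat-interval series
#'
#' Draws a beat train covering (at least) the configured duration. AF
#' intervals are independent draws from a truncated lognormal, reproducing
#' an irregularly irregular rhythm with no serial structure; SR intervals
#' follow the mean RR with sinusoidal respiratory modulation plus Gaussian
#' jitter. All intervals exceed 0.26 s.
#'
#' @param params A [rhythm_params()] object.
#' @return An `rr_series`: beat times starting at 0 (seconds), intervals,
#'   and all-`FALSE` PAC flags.
#' @export
simulate_rr <- function(params) {
  stopifnot(inherits(params, "rhythm_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  target <- params$duration + 3 * params$mean_rr
  if (params$rhythm == "AF") {
    cv <- params$rr_sd / params$mean_rr
    if (cv < 0.15)
      stop_ppgaf("'rr_sd' too small for AF: coefficient of variation must be >= 0.15",
                 "ppgaf_parameter_error")
    sdlog <- sqrt(log(1 + cv^2))
    meanlog <- log(params$mean_rr) - sdlog^2 / 2
    lo <- max(.RR_FLOOR + 0.04, 0.4 * params$mean_rr)
    hi <- 2.2 * params$mean_rr
    iv <- numeric(0)
    while (sum(iv) < target) {
      n_new <- max(32L, ceiling((target - sum(iv)) / params$mean_rr * 1.4))
      draw <- rlnorm(n_new, meanlog, sdlog)
      for (pass in 1:20) {          # resample out-of-range draws
        bad <- draw < lo | draw > hi
        if (!any(bad)) break
        draw[bad] <- rlnorm(sum(bad), meanlog, sdlog)
      }
      draw[draw < lo] <- lo; draw[draw > hi] <- hi
      iv <- c(iv, draw)
    }
  } else {
    iv <- numeric(0)
    t <- 0
    n_guess <- ceiling(target / params$mean_rr) + 16L
    iv <- numeric(n_guess); k <- 0L
    while (t < target) {
      k <- k + 1L
      if (k > length(iv)) iv <- c(iv, numeric(n_guess))
      mod <- 1 + params$resp_mod_depth * sin(2 * pi * params$resp_rate * t)
      r <- params$mean_rr * mod
      if (params$rr_sd > 0) r <- r + rnorm(1, 0, params$rr_sd)
      iv[k] <- max(r, .RR_FLOOR)
      t <- t + iv[k]
    }
    iv <- iv[seq_len(k)]
  }
  cum <- cumsum(iv)
  iv <- iv[seq_len(which(cum >= target)[1])]
  new_rr_series(cumsum(c(0, iv)), rhythm = params$rhythm)
}

#' Insert premature atrial complexes into a sinus-rhythm beat train
#'
#' Ectopic beats are inserted at Poisson-distributed random positions: the
#' PAC follows its anchor beat after `coupling_frac` times the local mean
#' RR (guaranteeing the 85\% rule fires, since the coupling fraction is
#' below 0.85), and the next sinus beat is delayed to a compensatory pause
#' of `compensatory_frac` times the local mean RR. The train is trimmed so
#' the total duration is preserved to within about one RR interval.
#'
#' @param rr An `rr_series` from an SR simulation.
#' @param params The [rhythm_params()] used to generate `rr`; `pac_rate`
#'   (PACs per minute) controls the expected count.
#' @return An `rr_series` with `pac_flags` marking the inserted beats.
#' @export
insert_pacs <- function(rr, params) {
  stopifnot(inherits(rr, "rr_series"), inherits(params, "rhythm_params"))
  if (params$rhythm == "AF" && params$pac_rate > 0)
    stop_ppgaf("'pac_rate' is only defined for SR rhythms: PACs are ectopy against sinus rhythm",
               "ppgaf_parameter_error")
  if (params$pac_rate == 0) return(rr)
  iv <- rr$intervals
  n_iv <- length(iv)
  total <- rr$beat_times[length(rr$beat_times)] - rr$beat_times[1]
  n_target <- rpois(1, params$pac_rate * total / 60)
  if (n_target == 0) return(rr)

  # anchor beats: interior, pairwise separated by >= 3 beats
  elig <- 3:(n_iv - 2)
  anchors <- integer(0)
  while (length(anchors) < n_target && length(elig) > 0) {
    a <- elig[sample.int(length(elig), 1)]
    anchors <- c(anchors, a)
    elig <- elig[abs(elig - a) > 2]
  }
  anchors <- sort(anchors)

  cf <- params$coupling_frac
  pieces <- vector("list", 2 * length(anchors) + 1)
  flag_pieces <- vector("list", 2 * length(anchors) + 1)
  prev <- 0L
  for (j in seq_along(anchors)) {
    a <- anchors[j]
    # window-scale local mean (~30 s) so the coupling margin against the
    # 85% rule holds for any analysis window containing the PAC
    rl <- mean(iv[max(1, a - 15):min(n_iv, a + 14)])
    cpl <- if (length(cf) == 2) runif(1, cf[1], cf[2]) else cf
    keep <- iv[(prev + 1L):(a - 1L)]
    pieces[[2 * j - 1]] <- keep
    flag_pieces[[2 * j - 1]] <- rep(FALSE, length(keep))
    pieces[[2 * j]] <- c(cpl * rl, params$compensatory_frac * rl)
    flag_pieces[[2 * j]] <- c(TRUE, FALSE)   # flag sits on the PAC beat
    prev <- a
  }
  pieces[[2 * length(anchors) + 1]] <- iv[(prev + 1L):n_iv]
  flag_pieces[[2 * length(anchors) + 1]] <- rep(FALSE, n_iv - prev)
  new_iv <- unlist(pieces)
  # flags are per-beat: beat k terminates interval k-1
  beat_flags <- c(FALSE, unlist(flag_pieces))
  bt <- cumsum(c(0, new_iv))
  keep <- bt <= total + 1e-9
  new_rr_series(bt[keep], beat_flags[keep], rhythm = rr$rhythm)
}

#' Render a PPG waveform from a beat train
#'
#' Each beat contributes a smooth two-component pulse: a systolic Gaussian
#' peak centred on the beat time and a smaller dicrotic bump. Pulse
#' amplitude is modulated by the preceding interval (a short interval
#' leaves less ventricular filling time, hence a smaller pulse), widths
#' scale with the available beat interval, and Gaussian noise is added at
#' `noise_sd`.
#'
#' @param rr An `rr_series`.
#' @param params A [rhythm_params()] object supplying `fs`, `duration`,
#'   `noise_sd` and `amp_slope`.
#' @return A `ppg_record`: samples, sampling rate, rhythm label, and
#'   ground-truth `beat_times` / `pac_flags` annotations.
#' @export
render_ppg <- function(rr, params) {
  stopifnot(inherits(rr, "rr_series"), inherits(params, "rhythm_params"))
  if (params$fs < 20)
    stop_ppgaf("'fs' below 20 Hz cannot represent the pulse template",
               "ppgaf_parameter_error")
  if (any(rr$intervals <= 0))
    stop_ppgaf("all intervals must be positive", "ppgaf_input_error")
  fs <- params$fs
  n_samp <- round(fs * params$duration)
  x <- numeric(n_samp)
  bt <- rr$beat_times
  iv <- rr$intervals
  med <- median(iv)
  n_b <- length(bt)
  use <- which(bt < params$duration + 2)
  for (k in use) {
    i_prev <- if (k > 1) iv[k - 1] else med
    i_next <- if (k < n_b) iv[k] else med
    amp <- max(0.3, 1 + params$amp_slope * (i_prev - med) / med)
    ic <- min(max(i_next, 0.4), 1.3)
    s_sys <- 0.10 * ic
    s_dic <- 0.16 * ic
    t_dic <- bt[k] + 0.35 * ic
    lo <- max(1L, floor((bt[k] - 5 * s_sys) * fs) + 1L)
    hi <- min(n_samp, ceiling((t_dic + 5 * s_dic) * fs) + 1L)
    if (lo > n_samp || hi < 1L) next
    tt <- (lo:hi - 1) / fs
    x[lo:hi] <- x[lo:hi] +
      amp * exp(-(tt - bt[k])^2 / (2 * s_sys^2)) +
      0.35 * amp * exp(-(tt - t_dic)^2 / (2 * s_dic^2))
  }
  if (params$noise_sd > 0) x <- x + rnorm(n_samp, 0, params$noise_sd)
  in_rec <- bt >= 0 & bt < params$duration
  structure(
    list(samples = x, fs = fs, patient_id = NA_character_,
         phase = NA_character_,
         label = if (is.na(rr$rhythm)) NA_character_ else rr$rhythm,
         beat_times = bt[in_rec], pac_flags = rr$pac_flags[in_rec],
         duration = params$duration),
    class = "ppg_record"
  )
}

#' @export
print.ppg_record <- function(x, ...) {
  cat(sprintf("<ppg_record> %s/%s: %.1f s at %g Hz (%d samples), %d annotated beats, %d PACs\n",
              x$patient_id, x$phase, x$duration, x$fs, length(x$samples),
              length(x$beat_times), sum(x$pac_flags)))
  invisible(x)
}

#' Simulate a full paired pre-/post-cardioversion cohort
#'
#' Every synthetic patient contributes one pre-cardioversion AF recording
#' and one post-cardioversion SR recording. Patient-level parameters (heart
#' rate, AF irregularity, respiratory modulation, waveform noise, PAC rate)
#' are drawn from realistic ranges so patients differ; a configurable
#' fraction of patients carries PACs, with rates drawn from a heavy-tailed
#' lognormal so that a minority of patients reaches high PAC burden. The
#' defaults were calibrated once so that roughly 30\% of post-cardioversion
#' 30-second windows contain at least one PAC.
#'
#' @param n_patients Number of patients (two recordings each).
#' @param duration Duration per recording, seconds.
#' @param fs Sampling rate, Hz.
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @param pac_positive_prob Probability that a patient exhibits any PACs
#'   after cardioversion.
#' @param pac_rate_meanlog,pac_rate_sdlog Lognormal parameters for the
#'   per-patient PAC rate (PACs/min) of PAC-positive patients.
#' @param pac_rate_cap Upper cap on the PAC rate, PACs/min.
#' @param noise_sd_range Range of per-recording waveform noise SD.
#' @return An `af_cohort`: list of `ppg_record`s plus the per-patient
#'   parameter table.
#' @export
#' @examples
#' coh <- generate_cohort(n_patients = 2, duration = 60, seed = 7)
#' coh
generate_cohort <- function(n_patients = 75, duration = 900, fs = 100,
                            seed = 1,
                            pac_positive_prob = 0.48,
                            pac_rate_meanlog = log(2.8),
                            pac_rate_sdlog = 1.3,
                            pac_rate_cap = 25,
                            noise_sd_range = c(0.03, 0.08)) {
  check_number(n_patients, "n_patients", lower = 1)
  check_number(seed, "seed")
  set.seed(seed)
  # phase 1: draw every patient-level parameter up front so the parameter
  # table is invariant to anything downstream (a change in one patient's
  # record randomness cannot reshuffle another patient's physiology)
  pt <- vector("list", n_patients)
  for (i in seq_len(n_patients)) {
    pac_u <- runif(1)
    pac_draw <- min(rlnorm(1, pac_rate_meanlog, pac_rate_sdlog), pac_rate_cap)
    pt[[i]] <- data.frame(
      patient_id = sprintf("P%03d", i),
      af_mean_rr = runif(1, 0.55, 0.80),
      af_cv = runif(1, 0.18, 0.30),
      sr_mean_rr = runif(1, 0.75, 1.05),
      sr_rr_sd = runif(1, 0.015, 0.04),
      resp_mod_depth = runif(1, 0.02, 0.06),
      pac_rate = if (pac_u < pac_positive_prob) pac_draw else 0,
      noise_sd_af = runif(1, noise_sd_range[1], noise_sd_range[2]),
      noise_sd_sr = runif(1, noise_sd_range[1], noise_sd_range[2]))
  }
  patients <- do.call(rbind, pt)

  # phase 2: simulate the paired recordings
  records <- vector("list", 2 * n_patients)
  for (i in seq_len(n_patients)) {
    pp <- patients[i, ]
    p_af <- rhythm_params("AF", mean_rr = pp$af_mean_rr,
                          rr_sd = pp$af_cv * pp$af_mean_rr,
                          noise_sd = pp$noise_sd_af, fs = fs,
                          duration = duration)
    p_sr <- rhythm_params("SR", mean_rr = pp$sr_mean_rr, rr_sd = pp$sr_rr_sd,
                          pac_rate = pp$pac_rate,
                          resp_mod_depth = pp$resp_mod_depth,
                          noise_sd = pp$noise_sd_sr, fs = fs,
                          duration = duration)
    rec_af <- render_ppg(simulate_rr(p_af), p_af)
    rec_af$patient_id <- pp$patient_id
    rec_af$phase <- "pre_dcc"; rec_af$label <- "AF"
    rec_sr <- render_ppg(insert_pacs(simulate_rr(p_sr), p_sr), p_sr)
    rec_sr$patient_id <- pp$patient_id
    rec_sr$phase <- "post_dcc"; rec_sr$label <- "SR"
    records[[2 * i - 1]] <- rec_af
    records[[2 * i]] <- rec_sr
  }
  structure(
    list(records = records, patients = patients,
         n_patients = n_patients, duration = duration, fs = fs, seed = seed),
    class = "af_cohort"
  )
}

#' @export
print.af_cohort <- function(x, ...) {
  cat(sprintf("<af_cohort> %d patients, %d recordings of %.0f s at %g Hz (seed %s)\n",
              x$n_patients, length(x$records), x$duration, x$fs,
              format(x$seed)))
  cat(sprintf("  PAC-positive patients: %d/%d\n",
              sum(x$patients$pac_rate > 0), x$n_patients))
  invisible(x)
}

#' Fraction of post-cardioversion windows containing at least one PAC
#'
#' Computed from the generator's ground-truth annotations using the same
#' windowing grid as [segment_ppg()].
#'
#' @param cohort An `af_cohort`.
#' @param win,overlap Window length and overlap, seconds.
#' @return Fraction in \[0, 1\].
#' @export
cohort_pac_window_prevalence <- function(cohort, win = 30, overlap = 20) {
  stopifnot(inherits(cohort, "af_cohort"))
  step <- win - overlap
  n_with <- 0L; n_tot <- 0L
  for (rec in cohort$records) {
    if (!identical(rec$phase, "post_dcc")) next
    starts <- seq(0, rec$duration - win, by = step)
    pac_t <- rec$beat_times[rec$pac_flags]
    hit <- vapply(starts, function(s) any(pac_t >= s & pac_t < s + win),
                  logical(1))
    n_with <- n_with + sum(hit)
    n_tot <- n_tot + length(starts)
  }
  n_with / n_tot
}
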