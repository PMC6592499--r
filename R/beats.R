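#' Detect pulse peaks in a normalised PPG window
#'
#' Beats are taken as local maxima of the filtered, z-scored signal that
#' exceed an adaptive amplitude threshold (a fraction of the typical
#' systolic peak height, which separates systolic peaks from the smaller
#' dicrotic bumps) subject to a refractory period. Candidate peaks are
#' accepted greedily in decreasing amplitude order, rejecting any peak
#' closer than `refractory` seconds to an already accepted one.
#'
#' @param x Numeric vector: one normalised window, or a `ppg_windows` row
#'   passed as a plain vector.
#' @param fs Sampling rate, Hz.
#' @param refractory Minimum inter-beat spacing, seconds (default 0.25,
#'   i.e. a 240 bpm ceiling).
#' @param thr_frac Threshold as a fraction of the reference systolic
#'   amplitude (median of the 20 tallest candidate peaks).
#' @return Strictly increasing beat times in seconds (relative to window
#'   start). Fewer than 3 detectable beats raises an
#'   `ppgaf_insufficient_beats` error.
#' @export
detect_beats <- function(x, fs, refractory = 0.25, thr_frac = 0.45) {
  if (!is.numeric(x) || length(x) < 3)
    stop_ppgaf("window must be a numeric vector", "ppgaf_input_error")
  check_number(fs, "fs", lower = 0, strict_lower = TRUE)
  n <- length(x)
  pk <- which(diff(sign(diff(x))) < 0) + 1L   # strict/plateau-left local maxima
  # a band-limited pulse train is smooth: a local-maxima density anywhere
  # near the upper band edge (18 Hz) means broadband noise, not pulses
  if (length(pk) / (n / fs) > 12)
    stop_ppgaf("no credible pulse train: local-maxima density is that of broadband noise",
               "ppgaf_insufficient_beats")
  pk <- pk[x[pk] > 0]                         # pulses rise above the z-score mean
  if (length(pk) < 3)
    stop_ppgaf("fewer than 3 candidate beats in window", "ppgaf_insufficient_beats")
  h <- x[pk]
  ref <- median(sort(h, decreasing = TRUE)[seq_len(min(20L, length(h)))])
  thr <- thr_frac * ref
  keep <- pk[h > thr]
  if (length(keep) < 3)
    stop_ppgaf("fewer than 3 beats above the adaptive threshold",
               "ppgaf_insufficient_beats")
  ord <- keep[order(x[keep], decreasing = TRUE)]
  min_gap <- round(refractory * fs)
  accepted <- integer(0)
  for (p in ord) {
    if (length(accepted) == 0 || all(abs(accepted - p) >= min_gap))
      accepted <- c(accepted, p)
  }
  if (length(accepted) < 3)
    stop_ppgaf("fewer than 3 beats after refractory pruning",
               "ppgaf_insufficient_beats")
  sort(accepted - 1) / fs
}

#' The premature-atrial-complex indicator (85\% rule)
#'
#' A beat is flagged as a PAC when its preceding inter-beat interval is
#' strictly less than `threshold` times the mean interval of the window.
#' The first beat has no preceding interval and can never be flagged.
#'
#' @param rr An `rr_series`, or a numeric vector of intervals in seconds.
#' @param threshold Fraction of the window-mean interval below which a beat
#'   is premature (default 0.85).
#' @return A `pac_result`: `n_beats`, `n_pac`, `burden = n_pac / n_beats`,
#'   and the per-beat logical `flags`.
#' @export
#' @examples
#' detect_pacs(c(0.8, 0.8, 0.8, 0.6, 1.0, 0.8))
detect_pacs <- function(rr, threshold = 0.85) {
  iv <- if (inherits(rr, "rr_series")) rr$intervals else rr
  if (!is.numeric(iv) || length(iv) < 2)
    stop_ppgaf("need at least 2 intervals (3 beats) for the PAC indicator",
               "ppgaf_insufficient_beats")
  check_number(threshold, "threshold", lower = 0, strict_lower = TRUE, upper = 1)
  m <- mean(iv)
  flags <- c(FALSE, iv < threshold * m)   # flag sits on the terminating beat
  n_beats <- length(iv) + 1L
  structure(
    list(n_beats = n_beats, n_pac = sum(flags), burden = sum(flags) / n_beats,
         flags = flags, threshold = threshold, mean_interval = m),
    class = "pac_result"
  )
}

#' @export
print.pac_result <- function(x, ...) {
  cat(sprintf("<pac_result> %d/%d beats flagged as PAC (burden %.1f%%), threshold %.0f%% of mean RR %.3f s\n",
              x$n_pac, x$n_beats, 100 * x$burden, 100 * x$threshold,
              x$mean_interval))
  invisible(x)
}

#' PAC burden of a window
#'
#' The number of PAC-flagged beats divided by the number of beats.
#'
#' @param result A `pac_result` from [detect_pacs()].
#' @return Fraction in \[0, 1\].
#' @export
pac_burden <- function(result) {
  stopifnot(inherits(result, "pac_result"))
  if (result$n_beats == 0)
    stop_ppgaf("burden undefined for zero beats", "ppgaf_input_error")
  result$n_pac / result$n_beats
}

#' Match detected beats to ground-truth annotations
#'
#' Greedy one-to-one matching in order of increasing time difference; a
#' pair matches when closer than `tol` seconds.
#'
#' @param detected,truth Beat times, seconds.
#' @param tol Matching tolerance, seconds.
#' @return List with integer vectors `det_idx`, `truth_idx` of matched
#'   pairs.
#' @keywords internal
match_beats <- function(detected, truth, tol = 0.15) {
  if (length(detected) == 0 || length(truth) == 0)
    return(list(det_idx = integer(0), truth_idx = integer(0)))
  d <- abs(outer(detected, truth, "-"))
  pairs <- which(d < tol, arr.ind = TRUE)
  if (nrow(pairs) == 0)
    return(list(det_idx = integer(0), truth_idx = integer(0)))
  pairs <- pairs[order(d[pairs]), , drop = FALSE]
  used_d <- logical(length(detected)); used_t <- logical(length(truth))
  di <- integer(0); ti <- integer(0)
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    if (!used_d[i] && !used_t[j]) {
      used_d[i] <- TRUE; used_t[j] <- TRUE
      di <- c(di, i); ti <- c(ti, j)
    }
  }
  list(det_idx = di, truth_idx = ti)
}

#' Validate the beat detector and PAC indicator against ground truth
#'
#' Runs [detect_beats()] and [detect_pacs()] over every window that carries
#' simulator annotations and scores (i) beat detection — the fraction of
#' true beats recovered within `tol` seconds (sensitivity) and the fraction
#' of detections matching a true beat (precision) — and (ii) the per-beat
#' PAC flags on matched beats: sensitivity (true PACs flagged) and
#' specificity (true sinus beats not flagged). PAC flags are scored on
#' SR-labelled windows only — the indicator quantifies ectopy against an
#' underlying sinus rhythm and is not defined during AF. A window's first
#' beat is excluded from PAC scoring because it has no preceding interval.
#'
#' @param windows A `ppg_windows` object with `truth` annotations.
#' @param threshold PAC-rule threshold, passed to [detect_pacs()].
#' @param tol Beat-matching tolerance, seconds.
#' @return List: `beat_sensitivity`, `beat_precision`,
#'   `pac_sensitivity`, `pac_specificity`, counts, and the number of
#'   windows skipped for insufficient beats.
#' @export
indicator_validation <- function(windows, threshold = 0.85, tol = 0.15) {
  stopifnot(inherits(windows, "ppg_windows"))
  if (is.null(windows$truth))
    stop_ppgaf("windows carry no ground-truth annotations", "ppgaf_input_error")
  n_true <- 0L; n_det <- 0L; n_match <- 0L
  tp <- fp <- tn <- fn <- 0L
  skipped <- 0L
  for (i in seq_len(nrow(windows$x))) {
    tr <- windows$truth[[i]]
    if (length(tr$beat_times) < 3) next
    bt <- tryCatch(detect_beats(windows$x[i, ], windows$fs),
                   ppgaf_insufficient_beats = function(e) NULL)
    if (is.null(bt)) { skipped <- skipped + 1L; next }
    m <- match_beats(bt, tr$beat_times, tol = tol)
    n_true <- n_true + length(tr$beat_times)
    n_det <- n_det + length(bt)
    n_match <- n_match + length(m$det_idx)
    if (!identical(windows$meta$label[i], "SR")) next
    pr <- detect_pacs(diff(bt), threshold = threshold)
    # score flags on matched beats, skipping each window's first beat
    for (k in seq_along(m$det_idx)) {
      if (m$det_idx[k] == 1L || m$truth_idx[k] == 1L) next
      pred <- pr$flags[m$det_idx[k]]
      truth_flag <- tr$pac_flags[m$truth_idx[k]]
      if (truth_flag && pred) tp <- tp + 1L
      else if (truth_flag && !pred) fn <- fn + 1L
      else if (!truth_flag && pred) fp <- fp + 1L
      else tn <- tn + 1L
    }
  }
  list(beat_sensitivity = n_match / n_true,
       beat_precision = n_match / n_det,
       pac_sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       pac_specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       counts = c(tp = tp, fp = fp, tn = tn, fn = fn,
                  true_beats = n_true, detected_beats = n_det,
                  matched_beats = n_match),
       skipped_windows = skipped)
}

#' Per-window beat and PAC summary for a window set
#'
#' @param windows A `ppg_windows` object.
#' @param threshold PAC-rule threshold.
#' @return Data frame: patient_id, window_index, label, n_beats, n_pac,
#'   burden (NA where fewer than 3 beats were detectable).
#' @export
pac_summary <- function(windows, threshold = 0.85) {
  stopifnot(inherits(windows, "ppg_windows"))
  n <- nrow(windows$x)
  out <- data.frame(windows$meta[, c("patient_id", "window_index", "label")],
                    n_beats = NA_integer_, n_pac = NA_integer_,
                    burden = NA_real_)
  for (i in seq_len(n)) {
    bt <- tryCatch(detect_beats(windows$x[i, ], windows$fs),
                   ppgaf_insufficient_beats = function(e) NULL)
    if (is.null(bt)) next
    pr <- detect_pacs(diff(bt), threshold = threshold)
    out$n_beats[i] <- pr$n_beats
    out$n_pac[i] <- pr$n_pac
    out$burden[i] <- pr$burden
  }
  out
}
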