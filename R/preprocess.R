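#' Remove the DC bias from a signal
#'
#' @param x Numeric vector.
#' @return `x - mean(x)`.
#' @export
remove_bias <- function(x) {
  if (!is.numeric(x) || length(x) == 0)
    stop_ppgaf("signal must be a non-empty numeric vector", "ppgaf_input_error")
  x - mean(x)
}

#' Zero-phase Butterworth band-pass filter
#'
#' A 4th-order Butterworth band-pass (default 0.2--18 Hz, the conventional
#' PPG band) applied forward and backward so the pass is zero-phase and
#' beat timing is preserved. The signal is extended by odd reflection
#' before filtering to suppress edge transients of the 0.2 Hz high-pass
#' corner; output length equals input length.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate, Hz. Must exceed `2 * hi`.
#' @param lo,hi Band edges, Hz.
#' @param order Butterworth prototype order.
#' @return Filtered signal, same length as `x`.
#' @export
bandpass <- function(x, fs, lo = 0.2, hi = 18, order = 4) {
  if (!is.numeric(x) || length(x) < 8)
    stop_ppgaf("signal must be a numeric vector of length >= 8", "ppgaf_input_error")
  check_number(fs, "fs", lower = 0, strict_lower = TRUE)
  if (fs <= 2 * hi)
    stop_ppgaf(sprintf("'fs' (%g Hz) must exceed twice the upper band edge (%g Hz)", fs, hi),
               "ppgaf_parameter_error")
  b <- signal::butter(order, c(lo, hi) / (fs / 2), type = "pass")
  n <- length(x)
  np <- min(n - 1L, ceiling(3 / lo * fs))
  pre <- 2 * x[1] - x[(np + 1):2]
  post <- 2 * x[n] - x[(n - 1):(n - np)]
  y <- signal::filtfilt(b, c(pre, x, post))
  y[(np + 1):(np + n)]
}

#' Z-score normalisation
#'
#' Centres and scales a window to zero mean and unit standard deviation
#' (population convention, i.e. the root mean square of the centred
#' samples), making windows invariant to the amplitude scale of the
#' sensor.
#'
#' @param x Numeric, non-constant.
#' @return Standardised vector.
#' @export
normalize_signal <- function(x) {
  if (!is.numeric(x) || length(x) < 2)
    stop_ppgaf("signal must be a numeric vector of length >= 2", "ppgaf_input_error")
  mu <- mean(x)
  s <- sqrt(mean((x - mu)^2))
  if (!is.finite(s) || s == 0)
    stop_ppgaf("cannot normalise a constant signal", "ppgaf_degenerate_input")
  (x - mu) / s
}

#' Segment a PPG recording into overlapping analysis windows
#'
#' Implements the conditioning pipeline: bias removal and zero-phase
#' band-pass on the full recording (filtering before segmentation avoids
#' per-window filter transients), then extraction of `win`-second windows
#' every `win - overlap` seconds, each z-scored independently. Window
#' labels are inherited from the recording phase. Ground-truth beat
#' annotations, when present, are carried along per window for validation.
#'
#' @param record A `ppg_record`.
#' @param win Window length in seconds (default 30).
#' @param overlap Overlap between consecutive windows in seconds
#'   (default 20).
#' @param lo,hi Band-pass edges in Hz.
#' @return A `ppg_windows` object: matrix `x` (windows in rows), metadata
#'   data frame `meta` (patient_id, phase, label, window_index,
#'   start_time), sampling rate `fs`, and `truth` (per-window list of
#'   ground-truth beat times relative to window start plus PAC flags, or
#'   `NULL`). A recording shorter than `win` yields zero windows with a
#'   warning.
#' @export
segment_ppg <- function(record, win = 30, overlap = 20, lo = 0.2, hi = 18) {
  stopifnot(inherits(record, "ppg_record"))
  check_number(win, "win", lower = 0, strict_lower = TRUE)
  check_number(overlap, "overlap", lower = 0, upper = win, strict_upper = TRUE)
  fs <- record$fs
  dur <- length(record$samples) / fs
  wlen <- round(win * fs)
  if (length(record$samples) < wlen) {
    warning(sprintf("recording %s/%s shorter than one window; returning no windows",
                    record$patient_id, record$phase))
    return(new_ppg_windows(matrix(numeric(0), 0, wlen), empty_meta(), fs, NULL))
  }
  step <- win - overlap
  starts <- seq(0, dur - win, by = step)
  filt <- bandpass(remove_bias(record$samples), fs, lo = lo, hi = hi)
  n_w <- length(starts)
  x <- matrix(NA_real_, n_w, wlen)
  truth <- if (!is.null(record$beat_times)) vector("list", n_w) else NULL
  for (i in seq_len(n_w)) {
    i0 <- round(starts[i] * fs)
    x[i, ] <- normalize_signal(filt[(i0 + 1):(i0 + wlen)])
    if (!is.null(truth)) {
      sel <- record$beat_times >= starts[i] & record$beat_times < starts[i] + win
      truth[[i]] <- list(beat_times = record$beat_times[sel] - starts[i],
                         pac_flags = record$pac_flags[sel])
    }
  }
  meta <- data.frame(patient_id = rep(record$patient_id, n_w),
                     phase = rep(record$phase, n_w),
                     label = rep(record$label, n_w),
                     window_index = seq_len(n_w),
                     start_time = starts,
                     stringsAsFactors = FALSE)
  new_ppg_windows(x, meta, fs, truth)
}

empty_meta <- function() {
  data.frame(patient_id = character(0), phase = character(0),
             label = character(0), window_index = integer(0),
             start_time = numeric(0), stringsAsFactors = FALSE)
}

new_ppg_windows <- function(x, meta, fs, truth) {
  structure(list(x = x, meta = meta, fs = fs, truth = truth),
            class = "ppg_windows")
}

#' @export
print.ppg_windows <- function(x, ...) {
  cat(sprintf("<ppg_windows> %d windows of %d samples at %g Hz",
              nrow(x$x), ncol(x$x), x$fs))
  if (nrow(x$meta) > 0) {
    tab <- table(x$meta$label)
    cat(" (", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), ")", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Expected number of windows for a recording duration
#'
#' `floor((duration - win) / (win - overlap)) + 1`.
#'
#' @param duration Recording duration, seconds.
#' @param win,overlap Window length and overlap, seconds.
#' @return Integer window count (0 if the recording is shorter than `win`).
#' @export
n_windows <- function(duration, win = 30, overlap = 20) {
  if (duration < win) return(0L)
  as.integer(floor((duration - win) / (win - overlap)) + 1)
}

#' Preprocess and segment an entire cohort
#'
#' Applies [segment_ppg()] to every recording and concatenates the results.
#'
#' @param cohort An `af_cohort` (or list of `ppg_record`s).
#' @param ... Passed to [segment_ppg()].
#' @return A `ppg_windows` object covering all recordings.
#' @export
preprocess_cohort <- function(cohort, ...) {
  records <- if (inherits(cohort, "af_cohort")) cohort$records else cohort
  parts <- lapply(records, segment_ppg, ...)
  x <- do.call(rbind, lapply(parts, `[[`, "x"))
  meta <- do.call(rbind, lapply(parts, `[[`, "meta"))
  rownames(meta) <- NULL
  truths <- lapply(parts, `[[`, "truth")
  truth <- if (all(vapply(truths, is.null, logical(1)))) NULL
           else do.call(c, truths)
  new_ppg_windows(x, meta, parts[[1]]$fs, truth)
}

#' Alias kept for symmetry with the single-record interface
#' @rdname segment_ppg
#' @export
preprocess_record <- segment_ppg
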