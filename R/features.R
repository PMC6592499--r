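#' Root-mean-square of successive RR-interval differences
#'
#' The classic irregularity feature: large under atrial fibrillation,
#' small in regular sinus rhythm.
#'
#' @param rr An `rr_series` or numeric vector of intervals (seconds).
#' @return RMSSD in seconds.
#' @export
rr_rmssd <- function(rr) {
  iv <- if (inherits(rr, "rr_series")) rr$intervals else rr
  if (!is.numeric(iv) || length(iv) < 2)
    stop_ppgaf("RMSSD needs at least 2 intervals", "ppgaf_insufficient_beats")
  sqrt(mean(diff(iv)^2))
}

#' Shannon entropy of the RR-interval histogram
#'
#' Intervals are binned into `n_bins` equal-width bins spanning the
#' window's own interval range; the entropy (nats) of the bin occupancy is
#' returned. Constant intervals occupy a single bin and give 0 by
#' convention; the maximum is `log(n_bins)`.
#'
#' @param rr An `rr_series` or numeric vector of intervals (seconds).
#' @param n_bins Number of histogram bins (default 16).
#' @return Entropy in nats, in `[0, log(n_bins)]`.
#' @export
rr_shannon_entropy <- function(rr, n_bins = 16) {
  iv <- if (inherits(rr, "rr_series")) rr$intervals else rr
  if (!is.numeric(iv) || length(iv) < 2)
    stop_ppgaf("entropy needs at least 2 intervals", "ppgaf_insufficient_beats")
  check_number(n_bins, "n_bins", lower = 2)
  rng <- range(iv)
  if (diff(rng) == 0) return(0)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  bin <- findInterval(iv, breaks, rightmost.closed = TRUE)
  p <- tabulate(bin, nbins = n_bins) / length(iv)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Autocorrelation features of a PPG window
#'
#' The normalised autocorrelation of the (already z-scored) window signal,
#' evaluated at `n_lags` equally spaced lags up to `max_lag` seconds. A
#' regular rhythm shows a strong peak near the beat period; AF decorrelates
#' quickly.
#'
#' @param x Numeric window (normalised samples).
#' @param fs Sampling rate, Hz.
#' @param max_lag Largest lag, seconds (default 3).
#' @param n_lags Number of lags (default 30).
#' @return Numeric vector of length `n_lags`, values in \[-1, 1\].
#' @export
acf_features <- function(x, fs, max_lag = 3, n_lags = 30) {
  if (!is.numeric(x) || length(x) < 2)
    stop_ppgaf("window must be a numeric vector", "ppgaf_input_error")
  if (sd(x) == 0)
    stop_ppgaf("autocorrelation undefined for a constant window",
               "ppgaf_degenerate_input")
  n <- length(x)
  lags <- round((1:n_lags) * max_lag / n_lags * fs)
  if (max(lags) >= n)
    stop_ppgaf("'max_lag' exceeds the window length", "ppgaf_parameter_error")
  x0 <- x - mean(x)
  denom <- sum(x0^2)
  vapply(lags, function(L) sum(x0[1:(n - L)] * x0[(1 + L):n]) / denom,
         numeric(1))
}

#' Feature table for a window set
#'
#' Runs beat detection on every window and assembles the baseline feature
#' matrix: RMSSD, Shannon entropy, the autocorrelation vector, and the
#' detected PAC burden. Features come from *detected* beats, mirroring
#' deployment conditions. Windows where beat detection fails (fewer than 3
#' beats) get `NA` interval features; [impute_features()] fills them before
#' model fitting.
#'
#' @param windows A `ppg_windows` object.
#' @param n_bins Entropy bins.
#' @param max_lag,n_lags Autocorrelation grid.
#' @param pac_threshold PAC-rule threshold used for the burden column.
#' @return Data frame: metadata columns, `rmssd`, `she`, `acf1..acfK`,
#'   `n_beats`, `n_pac`, `burden`.
#' @export
window_features <- function(windows, n_bins = 16, max_lag = 3, n_lags = 30,
                            pac_threshold = 0.85) {
  stopifnot(inherits(windows, "ppg_windows"))
  n <- nrow(windows$x)
  acf_mat <- matrix(NA_real_, n, n_lags,
                    dimnames = list(NULL, paste0("acf", seq_len(n_lags))))
  rmssd <- she <- burden <- rep(NA_real_, n)
  n_beats <- n_pac <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    xi <- windows$x[i, ]
    acf_mat[i, ] <- acf_features(xi, windows$fs, max_lag, n_lags)
    bt <- tryCatch(detect_beats(xi, windows$fs),
                   ppgaf_insufficient_beats = function(e) NULL)
    if (is.null(bt)) next
    iv <- diff(bt)
    if (length(iv) < 2) next
    rmssd[i] <- rr_rmssd(iv)
    she[i] <- rr_shannon_entropy(iv, n_bins = n_bins)
    pr <- detect_pacs(iv, threshold = pac_threshold)
    n_beats[i] <- pr$n_beats; n_pac[i] <- pr$n_pac; burden[i] <- pr$burden
  }
  cbind(windows$meta,
        data.frame(rmssd = rmssd, she = she), as.data.frame(acf_mat),
        data.frame(n_beats = n_beats, n_pac = n_pac, burden = burden))
}

#' Fill missing interval features with training medians
#'
#' @param x Feature matrix / data frame.
#' @param medians Optional named medians (from the training fold); computed
#'   from `x` when absent.
#' @return List with the completed matrix `x` and the `medians` used.
#' @export
impute_features <- function(x, medians = NULL) {
  x <- as.data.frame(x)
  num <- vapply(x, is.numeric, logical(1))
  if (is.null(medians))
    medians <- vapply(x[num], function(col) median(col, na.rm = TRUE), numeric(1))
  for (nm in names(x)[num]) {
    miss <- is.na(x[[nm]])
    if (any(miss)) x[[nm]][miss] <- medians[[nm]]
  }
  list(x = x, medians = medians)
}

feature_columns <- function(feature_set, n_lags = 30) {
  switch(feature_set,
    rmssd_she = c("rmssd", "she"),
    acf = paste0("acf", seq_len(n_lags)),
    ensemble = c("rmssd", "she", paste0("acf", seq_len(n_lags))),
    stop_ppgaf(sprintf("unknown feature set '%s'", feature_set),
               "ppgaf_parameter_error")
  )
}

#' Linear-kernel SVM baseline AF detector
#'
#' Fits the previously published detector family: a linear-kernel support
#' vector machine on (i) RMSSD + Shannon entropy, (ii) the autocorrelation
#' vector, or (iii) their concatenation (the ensemble). Features are
#' standardised with training-fold statistics; the decision value is
#' oriented so that larger scores mean AF.
#'
#' @param features Data frame from [window_features()] (or any frame with
#'   the required columns).
#' @param labels Factor or character vector of `"AF"` / `"SR"` labels.
#' @param feature_set `"rmssd_she"`, `"acf"` or `"ensemble"`.
#' @param cost SVM regularisation constant (default 1).
#' @param n_lags Autocorrelation vector length (for column selection).
#' @return An `af_svm` object with `predict`, `print` methods.
#' @export
af_svm <- function(features, labels, feature_set = c("rmssd_she", "acf", "ensemble"),
                   cost = 1, n_lags = 30) {
  feature_set <- match.arg(feature_set)
  labels <- factor(as.character(labels), levels = c("SR", "AF"))
  if (nlevels(droplevels(labels)) < 2)
    stop_ppgaf("training data must contain both classes", "ppgaf_input_error")
  cols <- feature_columns(feature_set, n_lags)
  missing_cols <- setdiff(cols, names(features))
  if (length(missing_cols) > 0)
    stop_ppgaf(paste0("missing feature columns: ",
                      paste(missing_cols, collapse = ", ")),
               "ppgaf_input_error")
  imp <- impute_features(features[, cols, drop = FALSE])
  x <- as.matrix(imp$x)
  fit <- e1071::svm(x, labels, kernel = "linear", cost = cost, scale = TRUE)
  dv <- attr(stats::predict(fit, x, decision.values = TRUE), "decision.values")[, 1]
  sign_flip <- if (mean(dv[labels == "AF"]) >= mean(dv[labels == "SR"])) 1 else -1
  structure(
    list(fit = fit, feature_set = feature_set, columns = cols,
         medians = imp$medians, sign = sign_flip, cost = cost,
         levels = c("SR", "AF")),
    class = "af_svm"
  )
}

#' @export
print.af_svm <- function(x, ...) {
  cat(sprintf("<af_svm> linear-kernel SVM on '%s' (%d features, %d support vectors, C = %g)\n",
              x$feature_set, length(x$columns), x$fit$tot.nSV, x$cost))
  invisible(x)
}

#' Predict with an SVM baseline
#'
#' @param object An `af_svm` model.
#' @param newdata Feature data frame with the model's columns.
#' @param ... Unused.
#' @return Data frame with `score` (oriented so larger means AF) and
#'   `predicted` (`"AF"`/`"SR"` factor).
#' @export
predict.af_svm <- function(object, newdata, ...) {
  x <- as.matrix(impute_features(newdata[, object$columns, drop = FALSE],
                                 object$medians)$x)
  pred <- stats::predict(object$fit, x, decision.values = TRUE)
  score <- object$sign * attr(pred, "decision.values")[, 1]
  data.frame(score = score,
             predicted = factor(as.character(pred), levels = object$levels))
}
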