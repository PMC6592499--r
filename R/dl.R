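#' Configuration for a compact deep AF classifier
#'
#' Fixes the architecture and training hyperparameters. The convolutional
#' model is a stack of exactly six 1-D convolution blocks (convolution,
#' ReLU, temporal downsampling by the stride) followed by global average
#' pooling and a 2-unit softmax head; the recurrent model is a single GRU
#' layer reading the window as a sequence of short frames, its final hidden
#' state feeding the same 2-unit softmax head. Both are deliberately
#' lightweight (well under 10^6 parameters) and train on one CPU.
#'
#' @param arch `"cnn"` or `"rnn"`.
#' @param fs Input sampling rate the model expects, Hz. Windows recorded at
#'   another rate are resampled by [dl_input()]; 40 Hz retains the full
#'   0.2--18 Hz content of the conditioned signal.
#' @param win Window length, seconds.
#' @param channels CNN: output channels of the six convolution blocks.
#' @param kernel,stride CNN kernel width and temporal stride (a scalar, or
#'   one stride per layer; the default downsamples aggressively at the
#'   first layer where the signal is still oversampled).
#' @param frame RNN: samples per input token (frame); the default reads the
#'   window as twenty 1.5-second frames.
#' @param hidden RNN: GRU hidden size.
#' @param lr Adam learning rate (`NULL`: 1e-3 for the CNN, 3e-3 for the
#'   RNN).
#' @param batch_size Minibatch size.
#' @param epochs Training epochs (`NULL`: 3 for both architectures — enough
#'   for convergence on cohort-scale data).
#' @param seed Integer seed controlling weight initialisation and batch
#'   shuffling; identical seed, data and config give identical weights.
#' @return An `af_net_config` list.
#' @export
af_net_config <- function(arch = c("cnn", "rnn"), fs = 40, win = 30,
                          channels = c(8, 16, 16, 16, 16, 16),
                          kernel = 7, stride = c(4, 2, 2, 2, 2, 2),
                          frame = 60, hidden = 32,
                          lr = NULL, batch_size = 256, epochs = NULL,
                          seed = 1) {
  arch <- match.arg(arch)
  if (is.null(lr)) lr <- if (arch == "cnn") 1e-3 else 3e-3
  if (is.null(epochs)) epochs <- 3
  if (arch == "cnn" && length(channels) != 6)
    stop_ppgaf("the convolutional classifier has exactly 6 convolution layers",
               "ppgaf_parameter_error")
  check_number(kernel, "kernel", lower = 1)
  if (!is.numeric(stride) || !length(stride) %in% c(1L, length(channels)) ||
      any(stride < 1))
    stop_ppgaf("'stride' must be a positive scalar or one stride per layer",
               "ppgaf_parameter_error")
  check_number(hidden, "hidden", lower = 1)
  check_number(frame, "frame", lower = 1)
  check_number(lr, "lr", lower = 0, strict_lower = TRUE)
  check_number(batch_size, "batch_size", lower = 1)
  check_number(epochs, "epochs", lower = 1)
  input_len <- round(fs * win)
  if (arch == "rnn" && input_len %% frame != 0)
    stop_ppgaf("window length must be a multiple of the RNN frame length",
               "ppgaf_parameter_error")
  structure(list(arch = arch, fs = fs, win = win, input_len = input_len,
                 channels = channels, kernel = kernel, stride = stride,
                 frame = frame, hidden = hidden, lr = lr,
                 batch_size = batch_size, epochs = epochs, seed = seed),
            class = "af_net_config")
}

#' Resample conditioned windows to the classifier input rate
#'
#' Linear-interpolation resampling of each window row from `fs_in` to
#' `fs_out`. The conditioned signal is band-limited to 18 Hz, so 40 Hz
#' (the default model rate) loses nothing.
#'
#' @param windows A `ppg_windows` object or a numeric matrix of windows in
#'   rows.
#' @param fs_in Input rate (taken from the `ppg_windows` object when
#'   given).
#' @param fs_out Output rate, Hz.
#' @param win Window length, seconds.
#' @return Matrix with `round(win * fs_out)` columns.
#' @export
dl_input <- function(windows, fs_out = 40, fs_in = NULL, win = 30) {
  if (inherits(windows, "ppg_windows")) {
    fs_in <- windows$fs
    x <- windows$x
  } else {
    x <- as.matrix(windows)
    if (is.null(fs_in))
      stop_ppgaf("'fs_in' must be given for a plain matrix", "ppgaf_input_error")
  }
  if (fs_in == fs_out) return(x)
  n_out <- round(win * fs_out)
  t_out <- (seq_len(n_out) - 1) / fs_out
  pos <- t_out * fs_in + 1
  lo <- pmin(floor(pos), ncol(x) - 1)
  w <- pos - lo
  x[, lo, drop = FALSE] * rep(1 - w, each = nrow(x)) +
    x[, lo + 1, drop = FALSE] * rep(w, each = nrow(x))
}

#' Fit a compact deep AF classifier
#'
#' Trains the configured architecture by minimising the softmax
#' cross-entropy between predicted and true window labels with
#' backpropagation (Adam). Training is deterministic given the seed in
#' `config`.
#'
#' @param x Numeric matrix, one conditioned window per row at the config's
#'   sampling rate (see [dl_input()]).
#' @param y Labels, `"AF"` / `"SR"` (factor or character). AF is the
#'   positive class.
#' @param arch `"cnn"` or `"rnn"`; ignored when `config` is given.
#' @param config An [af_net_config()], or a list of overrides of its
#'   defaults.
#' @param verbose Print the loss once per epoch.
#' @return An `af_net` model with `predict`, `print`, `summary` and `plot`
#'   methods.
#' @export
#' @examples
#' \donttest{
#' coh <- generate_cohort(n_patients = 2, duration = 120, seed = 3)
#' w <- preprocess_cohort(coh)
#' x <- dl_input(w)
#' fit <- af_net(x, w$meta$label, arch = "cnn",
#'               config = list(epochs = 1))
#' head(predict(fit, x))
#' }
af_net <- function(x, y, arch = c("cnn", "rnn"), config = list(),
                   verbose = FALSE) {
  if (inherits(config, "af_net_config")) {
    cfg <- config
  } else {
    arch <- match.arg(arch)
    cfg <- do.call(af_net_config, c(list(arch = arch), config))
  }
  x <- as.matrix(x)
  if (ncol(x) != cfg$input_len)
    stop_ppgaf(sprintf("windows have %d samples but the config expects %d",
                       ncol(x), cfg$input_len), "ppgaf_input_error")
  y <- factor(as.character(y), levels = c("SR", "AF"))
  if (any(is.na(y)))
    stop_ppgaf("labels must be 'AF' or 'SR'", "ppgaf_input_error")
  if (nlevels(droplevels(y)) < 2)
    stop_ppgaf("training data must contain both classes", "ppgaf_input_error")
  y01 <- as.integer(y == "AF")   # column 2 of the softmax is AF
  n <- nrow(x)

  set.seed(cfg$seed)
  pars <- if (cfg$arch == "cnn")
    cnn_init(cfg$input_len, cfg$channels, cfg$kernel, cfg$stride)
  else gru_init(cfg$frame, cfg$hidden)
  state <- adam_init(pars)
  epoch_loss <- numeric(cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    losses <- numeric(0)
    for (b0 in seq(1, n, by = cfg$batch_size)) {
      idx <- ord[b0:min(b0 + cfg$batch_size - 1, n)]
      fwd <- nn_forward(cfg$arch, pars, x[idx, , drop = FALSE], cfg,
                        want_cache = TRUE)
      sm <- softmax_xent(fwd$logits, y01[idx])
      if (!is.finite(sm$loss))
        stop_ppgaf(sprintf("non-finite training loss at epoch %d; lower the learning rate", ep),
                   "ppgaf_training_error")
      grads <- nn_backward(cfg$arch, pars, cfg, fwd, sm$dlogits)
      upd <- adam_step(pars, grads, state, lr = cfg$lr)
      pars <- upd$pars; state <- upd$state
      losses <- c(losses, sm$loss)
    }
    epoch_loss[ep] <- mean(losses)
    if (verbose)
      message(sprintf("epoch %d/%d: loss %.4f", ep, cfg$epochs, epoch_loss[ep]))
  }
  structure(
    list(pars = pars, config = cfg, levels = c("SR", "AF"),
         loss = epoch_loss, n_train = n,
         n_parameters = n_parameters(pars)),
    class = "af_net"
  )
}

#' Predict AF/SR diagnoses with confidence levels
#'
#' @param object A fitted [af_net()] model.
#' @param x Window matrix at the model's input rate and length.
#' @param type `"diagnosis"` for the full per-window frame (class
#'   probabilities, predicted label, confidence level), `"prob"` for the
#'   probability matrix, `"score"` for the AF probability alone.
#' @param batch_size Prediction batch size.
#' @param ... Unused.
#' @return See `type`. The confidence level is `100 * max(p_af, p_sr)`,
#'   between 50 and 100.
#' @export
predict.af_net <- function(object, x, type = c("diagnosis", "prob", "score"),
                           batch_size = 1024, ...) {
  type <- match.arg(type)
  x <- as.matrix(x)
  cfg <- object$config
  if (ncol(x) != cfg$input_len)
    stop_ppgaf(sprintf("windows have %d samples but the model expects %d",
                       ncol(x), cfg$input_len), "ppgaf_input_error")
  n <- nrow(x)
  p <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("p_sr", "p_af")))
  for (b0 in seq(1, n, by = batch_size)) {
    idx <- b0:min(b0 + batch_size - 1, n)
    fwd <- nn_forward(cfg$arch, object$pars, x[idx, , drop = FALSE], cfg)
    p[idx, ] <- softmax_rows(fwd$logits)
  }
  if (type == "prob") return(p)
  if (type == "score") return(p[, "p_af"])
  data.frame(
    p_af = p[, "p_af"], p_sr = p[, "p_sr"],
    predicted = factor(ifelse(p[, "p_af"] >= p[, "p_sr"], "AF", "SR"),
                       levels = c("SR", "AF")),
    cl = confidence_level(p[, c("p_af", "p_sr")])
  )
}

#' @export
print.af_net <- function(x, ...) {
  cfg <- x$config
  desc <- if (cfg$arch == "cnn")
    sprintf("6-layer 1D-CNN (kernel %d, stride %d, channels %s)",
            cfg$kernel, cfg$stride, paste(cfg$channels, collapse = "-"))
  else
    sprintf("single-layer GRU (frame %d, hidden %d)", cfg$frame, cfg$hidden)
  cat(sprintf("<af_net> %s + 2-unit softmax head\n", desc))
  cat(sprintf("  %s parameters, trained %d epochs on %d windows (final loss %.4f)\n",
              format(x$n_parameters, big.mark = ","), cfg$epochs, x$n_train,
              tail(x$loss, 1)))
  invisible(x)
}

#' @export
summary.af_net <- function(object, ...) {
  print(object)
  cat("  epoch losses:", paste(sprintf("%.4f", object$loss), collapse = ", "), "\n")
  invisible(object)
}

#' @export
plot.af_net <- function(x, ...) {
  plot(seq_along(x$loss), x$loss, type = "b", xlab = "epoch",
       ylab = "training cross-entropy", main = "af_net training loss", ...)
  invisible(x)
}

#' Confidence level of a two-class softmax output
#'
#' The confidence level (CL) is 100 times the larger of the two class
#' probabilities. Its minimum is 50\% (an uninformative coin-flip output)
#' and its maximum is 100\% (all mass on one class). It is symmetric in the
#' pair: the CL quantifies how decided the diagnosis is, not which class
#' was chosen.
#'
#' @param p A probability pair (length-2 numeric), or a two-column matrix /
#'   data frame of pairs (one prediction per row). Each pair must be
#'   non-negative and sum to 1 within `tol`.
#' @param tol Tolerance on the unit sum.
#' @return Confidence level(s) in percent, in \[50, 100\].
#' @export
#' @examples
#' confidence_level(c(0.5, 0.5))   # 50
#' confidence_level(c(0.9, 0.1))   # 90
#' confidence_level(c(1, 0))       # 100
confidence_level <- function(p, tol = 1e-6) {
  if (is.data.frame(p)) p <- as.matrix(p)
  if (is.null(dim(p))) {
    if (length(p) != 2)
      stop_ppgaf("a probability pair has exactly 2 entries", "ppgaf_input_error")
    p <- matrix(p, 1, 2)
  }
  if (ncol(p) != 2)
    stop_ppgaf("expected two class-probability columns", "ppgaf_input_error")
  if (any(!is.finite(p)) || any(p < -tol))
    stop_ppgaf("probabilities must be finite and non-negative",
               "ppgaf_probability_error")
  if (any(abs(rowSums(p) - 1) > tol))
    stop_ppgaf("class probabilities must sum to 1", "ppgaf_probability_error")
  unname(100 * pmax(p[, 1], p[, 2]))
}
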