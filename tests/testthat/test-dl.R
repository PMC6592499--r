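numeric_grad <- function(arch, pars, cfg, X, y01, nm, i, eps = 1e-5) {
  f <- function(p) {
    fwd <- ppgaf:::nn_forward(arch, p, X, cfg)
    ppgaf:::softmax_xent(fwd$logits, y01)$loss
  }
  p2 <- pars
  p2[[nm]][i] <- p2[[nm]][i] + eps
  up <- f(p2)
  p2[[nm]][i] <- p2[[nm]][i] - 2 * eps
  dn <- f(p2)
  (up - dn) / (2 * eps)
}

test_that("analytic gradients match numeric differentiation for both architectures", {
  set.seed(9)
  cases <- list(
    list(arch = "cnn",
         cfg = af_net_config("cnn", fs = 40, win = 10,
                             channels = c(3, 4, 4, 4, 4, 4), kernel = 5,
                             stride = c(3, 2, 2, 2, 2, 1)),
         L = 400),
    list(arch = "rnn",
         cfg = af_net_config("rnn", fs = 4, win = 30, frame = 10, hidden = 7),
         L = 120)
  )
  for (cs in cases) {
    X <- matrix(rnorm(6 * cs$L), 6, cs$L)
    y01 <- c(0L, 1L, 1L, 0L, 1L, 0L)
    pars <- if (cs$arch == "cnn")
      ppgaf:::cnn_init(cs$L, cs$cfg$channels, cs$cfg$kernel, cs$cfg$stride)
    else ppgaf:::gru_init(cs$cfg$frame, cs$cfg$hidden)
    fwd <- ppgaf:::nn_forward(cs$arch, pars, X, cs$cfg, want_cache = TRUE)
    sm <- ppgaf:::softmax_xent(fwd$logits, y01)
    gr <- ppgaf:::nn_backward(cs$arch, pars, cs$cfg, fwd, sm$dlogits)
    for (nm in names(pars)) {
      idx <- sample(length(pars[[nm]]), min(4, length(pars[[nm]])))
      for (i in idx) {
        ng <- numeric_grad(cs$arch, pars, cs$cfg, X, y01, nm, i)
        expect_equal(gr[[nm]][i], ng, tolerance = 1e-4,
                     label = sprintf("%s %s[%d]", cs$arch, nm, i))
      }
    }
  }
})

test_that("forward passes return row-normalised probabilities of shape (batch, 2)", {
  set.seed(10)
  X <- matrix(rnorm(8 * 1200), 8, 1200)
  for (arch in c("cnn", "rnn")) {
    cfg <- af_net_config(arch)
    pars <- if (arch == "cnn")
      ppgaf:::cnn_init(1200, cfg$channels, cfg$kernel, cfg$stride)
    else ppgaf:::gru_init(cfg$frame, cfg$hidden)
    p <- ppgaf:::softmax_rows(ppgaf:::nn_forward(arch, pars, X, cfg)$logits)
    expect_equal(dim(p), c(8L, 2L))
    expect_equal(rowSums(p), rep(1, 8))
    expect_true(all(p >= 0))
    # untrained symmetric-scale initialisation is nearly uninformative:
    # confidence concentrates near the 50% floor
    expect_lt(mean(confidence_level(p)), 65)
    expect_lt(max(confidence_level(p)), 90)
    # lightweight contract
    expect_lt(ppgaf:::n_parameters(pars), 1e6)
  }
})

test_that("the configuration guards the 6-layer convolutional contract", {
  expect_error(af_net_config("cnn", channels = c(8, 16, 16)),
               class = "ppgaf_parameter_error")
  expect_error(af_net_config("rnn", frame = 37), # 1200 not divisible
               class = "ppgaf_parameter_error")
  expect_silent(af_net_config("rnn"))
})

test_that("both classifiers drive the loss down and solve a separable toy problem", {
  set.seed(12)
  t <- (0:1199) / 40
  proto_a <- sin(2 * pi * 1.1 * t)
  proto_b <- sin(2 * pi * 0.7 * t) + 0.5 * sin(2 * pi * 2.1 * t)
  n <- 30
  X <- rbind(matrix(rep(proto_a, n), n, byrow = TRUE),
             matrix(rep(proto_b, n), n, byrow = TRUE)) +
    matrix(rnorm(2 * n * 1200, sd = 0.05), 2 * n)
  y <- rep(c("AF", "SR"), each = n)
  for (arch in c("cnn", "rnn")) {
    fit <- af_net(X, y, arch, config = list(epochs = 6, batch_size = 16))
    expect_lt(tail(fit$loss, 1), fit$loss[1])
    pr <- predict(fit, X)
    expect_equal(mean(as.character(pr$predicted) == y), 1)
  }
})

test_that("training on shuffled labels gives chance-level held-out AUC", {
  ds <- frozen_dataset()
  set.seed(13)
  idx <- sample(nrow(ds$x_dl), 1200)
  tr <- idx[1:800]; te <- idx[801:1200]
  y_perm <- sample(as.character(ds$labels[tr]))
  fit <- af_net(ds$x_dl[tr, ], y_perm, "rnn", config = list(epochs = 2))
  auc <- auc_mw(predict(fit, ds$x_dl[te, ], type = "score"), ds$labels[te])
  expect_gt(auc, 0.38)
  expect_lt(auc, 0.62)
})

test_that("identical seed, data and config give identical weights and predictions", {
  set.seed(14)
  X <- matrix(rnorm(40 * 1200), 40, 1200)
  y <- rep(c("AF", "SR"), 20)
  f1 <- af_net(X, y, "cnn", config = list(epochs = 1, seed = 5))
  f2 <- af_net(X, y, "cnn", config = list(epochs = 1, seed = 5))
  expect_identical(f1$pars, f2$pars)
  expect_identical(predict(f1, X), predict(f2, X))
})

test_that("prediction refuses windows of the wrong length", {
  set.seed(15)
  X <- matrix(rnorm(20 * 1200), 20, 1200)
  y <- rep(c("AF", "SR"), 10)
  fit <- af_net(X, y, "rnn", config = list(epochs = 1))
  expect_error(predict(fit, matrix(rnorm(600), 1)), class = "ppgaf_input_error")
})

test_that("training data must contain both classes", {
  X <- matrix(rnorm(10 * 1200), 10, 1200)
  expect_error(af_net(X, rep("AF", 10), "cnn"), class = "ppgaf_input_error")
})

test_that("dl_input resamples to the model rate without distorting slow content", {
  w <- small_windows()
  x40 <- dl_input(w)
  expect_equal(dim(x40), c(nrow(w$x), 1200))
  # a pure 1 Hz tone survives the 100 -> 40 Hz resampling
  tone <- sin(2 * pi * 1 * (0:2999) / 100)
  r <- dl_input(matrix(tone, 1), fs_in = 100)
  expect_equal(as.numeric(r), sin(2 * pi * 1 * (0:1199) / 40), tolerance = 1e-3)
})

test_that("the confidence level is the larger softmax probability in percent", {
  expect_equal(confidence_level(c(0.5, 0.5)), 50)
  expect_equal(confidence_level(c(0.9, 0.1)), 90)
  expect_equal(confidence_level(c(1, 0)), 100)
  expect_equal(confidence_level(c(0.02, 0.98)), 98)
  m <- matrix(c(0.3, 0.7, 0.6, 0.4), 2, byrow = TRUE)
  expect_equal(confidence_level(m), c(70, 60))
  # symmetry and bounds over random pairs
  set.seed(16)
  p1 <- runif(200)
  cls <- confidence_level(cbind(p1, 1 - p1))
  expect_identical(cls, confidence_level(cbind(1 - p1, p1)))
  expect_true(all(cls >= 50 & cls <= 100))
  expect_error(confidence_level(c(0.5, 0.6)), class = "ppgaf_probability_error")
  expect_error(confidence_level(c(-0.1, 1.1)), class = "ppgaf_probability_error")
})

test_that("diagnoses carry coherent probabilities, labels and confidence", {
  set.seed(17)
  X <- matrix(rnorm(30 * 1200), 30, 1200)
  y <- rep(c("AF", "SR"), 15)
  fit <- af_net(X, y, "rnn", config = list(epochs = 1))
  d <- predict(fit, X)
  expect_named(d, c("p_af", "p_sr", "predicted", "cl"))
  expect_equal(d$p_af + d$p_sr, rep(1, 30))
  expect_identical(as.character(d$predicted),
                   ifelse(d$p_af >= d$p_sr, "AF", "SR"))
  expect_equal(d$cl, 100 * pmax(d$p_af, d$p_sr))
})
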