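# Internal neural-network engine: a 6-block 1-D convolutional stack and a
# single-layer GRU, trained by backpropagation with Adam. Implemented on
# top of BLAS matrix products (convolutions decomposed into one shifted
# matrix product per kernel tap) so that CPU training at cohort scale is
# fast and bit-reproducible under a fixed seed.

sigmoid <- function(x) 1 / (1 + exp(-x))

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# parameters are a flat named list of arrays; Adam walks the names
adam_init <- function(pars) {
  list(m = lapply(pars, function(p) p * 0),
       v = lapply(pars, function(p) p * 0),
       t = 0L)
}

adam_step <- function(pars, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(pars)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    pars[[nm]] <- pars[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(pars = pars, state = state)
}

# ---- 1-D CNN ----------------------------------------------------------

conv_out_len <- function(L, k, s) (L - k) %/% s + 1L

layer_stride <- function(cfg, l) {
  s <- cfg$stride
  if (length(s) == 1) s else s[l]
}

cnn_init <- function(input_len, channels, kernel, stride) {
  n_layers <- length(channels)
  if (length(stride) == 1) stride <- rep(stride, n_layers)
  pars <- list()
  cin <- 1L
  L <- input_len
  for (l in seq_len(n_layers)) {
    cout <- channels[l]
    pars[[sprintf("conv%d.W", l)]] <-
      array(rnorm(kernel * cin * cout, sd = sqrt(2 / (kernel * cin))),
            dim = c(kernel, cin, cout))
    pars[[sprintf("conv%d.b", l)]] <- numeric(cout)
    L <- conv_out_len(L, kernel, stride[l])
    if (L < 1)
      stop_ppgaf("input too short for the configured convolution stack",
                 "ppgaf_parameter_error")
    cin <- cout
  }
  pars[["dense.W"]] <- matrix(rnorm(cin * 2, sd = sqrt(1 / cin)), cin, 2)
  pars[["dense.b"]] <- numeric(2)
  pars
}

# gather the strided k-tap neighbourhoods of every output position into an
# im2col matrix (B*outL, k*cin); one BLAS product then evaluates the layer
im2col <- function(a, k, s, outL) {
  B <- dim(a)[1]; cin <- dim(a)[3]
  pos <- as.vector(outer(seq.int(0L, by = s, length.out = outL), 1:k, "+"))
  xs <- a[, pos, , drop = FALSE]          # (B, outL*k, cin), outL fastest
  dim(xs) <- c(B * outL, k * cin)
  xs
}

cnn_forward <- function(pars, X, cfg, want_cache = FALSE) {
  B <- nrow(X)
  k <- cfg$kernel
  a <- array(X, c(B, ncol(X), 1L))
  n_layers <- length(cfg$channels)
  caches <- if (want_cache) vector("list", n_layers) else NULL
  for (l in seq_len(n_layers)) {
    W <- pars[[sprintf("conv%d.W", l)]]
    b <- pars[[sprintf("conv%d.b", l)]]
    s <- layer_stride(cfg, l)
    cin <- dim(W)[2]; cout <- dim(W)[3]
    outL <- conv_out_len(dim(a)[2], k, s)
    xs <- im2col(a, k, s, outL)
    Wm <- W; dim(Wm) <- c(k * cin, cout)
    z <- xs %*% Wm + matrix(b, B * outL, cout, byrow = TRUE)
    if (want_cache) caches[[l]] <- list(xs = xs, z = z, outL = outL,
                                        L_in = dim(a)[2])
    r <- z; r[r < 0] <- 0
    a <- array(r, c(B, outL, cout))
  }
  outL <- dim(a)[2]; cout <- dim(a)[3]
  pooled <- colMeans(aperm(a, c(2, 1, 3)))        # mean over time
  dim(pooled) <- c(B, cout)
  logits <- pooled %*% pars[["dense.W"]] +
    matrix(pars[["dense.b"]], B, 2, byrow = TRUE)
  list(logits = logits, pooled = pooled, caches = caches, outL = outL)
}

cnn_backward <- function(pars, cfg, fwd, dlogits) {
  B <- nrow(dlogits)
  k <- cfg$kernel
  grads <- list()
  grads[["dense.W"]] <- crossprod(fwd$pooled, dlogits)
  grads[["dense.b"]] <- colSums(dlogits)
  dpooled <- dlogits %*% t(pars[["dense.W"]])
  cout <- ncol(dpooled)
  da <- aperm(array(dpooled / fwd$outL, c(B, cout, fwd$outL)), c(1, 3, 2))
  for (l in rev(seq_along(fwd$caches))) {
    cc <- fwd$caches[[l]]
    W <- pars[[sprintf("conv%d.W", l)]]
    s <- layer_stride(cfg, l)
    cin <- dim(W)[2]; cout <- dim(W)[3]
    outL <- cc$outL
    dz <- matrix(da, B * outL, cout)
    dz[cc$z <= 0] <- 0
    grads[[sprintf("conv%d.b", l)]] <- colSums(dz)
    dW <- crossprod(cc$xs, dz)              # (k*cin, cout)
    dim(dW) <- c(k, cin, cout)
    grads[[sprintf("conv%d.W", l)]] <- dW
    if (l > 1) {                            # input gradient unused at l = 1
      Wm <- W; dim(Wm) <- c(k * cin, cout)
      dxs <- dz %*% t(Wm)                   # (B*outL, k*cin)
      dim(dxs) <- c(B, outL, k, cin)
      d_in <- array(0, c(B, cc$L_in, cin))
      for (j in seq_len(k)) {
        idx <- seq.int(j, by = s, length.out = outL)
        contrib <- dxs[, , j, , drop = FALSE]
        dim(contrib) <- c(B, outL, cin)
        d_in[, idx, ] <- d_in[, idx, , drop = FALSE] + contrib
      }
      da <- d_in
    }
  }
  grads
}

# ---- single-layer GRU -------------------------------------------------

gru_init <- function(frame, hidden) {
  list(
    "gru.U" = matrix(rnorm(frame * 3 * hidden, sd = sqrt(1 / frame)),
                     frame, 3 * hidden),
    "gru.Wh" = matrix(rnorm(hidden * 3 * hidden, sd = sqrt(1 / hidden)),
                      hidden, 3 * hidden),
    "gru.b" = numeric(3 * hidden),
    "dense.W" = matrix(rnorm(hidden * 2, sd = sqrt(1 / hidden)), hidden, 2),
    "dense.b" = numeric(2)
  )
}

gru_forward <- function(pars, X, cfg, want_cache = FALSE) {
  B <- nrow(X)
  D <- cfg$frame; H <- cfg$hidden
  TT <- ncol(X) %/% D
  X3 <- array(t(X), c(D, TT, B))        # frame-major slicing per step
  U <- pars[["gru.U"]]; Wh <- pars[["gru.Wh"]]; b <- pars[["gru.b"]]
  iz <- 1:H; ir <- (H + 1):(2 * H); in_ <- (2 * H + 1):(3 * H)
  h <- matrix(0, B, H)
  caches <- if (want_cache) vector("list", TT) else NULL
  for (t in seq_len(TT)) {
    xt <- t(matrix(X3[, t, ], D, B))    # (B, D)
    gx <- xt %*% U
    gh <- h %*% Wh
    z <- sigmoid(gx[, iz] + gh[, iz] + matrix(b[iz], B, H, byrow = TRUE))
    r <- sigmoid(gx[, ir] + gh[, ir] + matrix(b[ir], B, H, byrow = TRUE))
    n <- tanh(gx[, in_] + r * gh[, in_] + matrix(b[in_], B, H, byrow = TRUE))
    h_new <- (1 - z) * h + z * n
    if (want_cache) caches[[t]] <- list(xt = xt, h_prev = h, z = z, r = r,
                                        n = n, ghn = gh[, in_])
    h <- h_new
  }
  logits <- h %*% pars[["dense.W"]] +
    matrix(pars[["dense.b"]], B, 2, byrow = TRUE)
  list(logits = logits, h = h, caches = caches)
}

gru_backward <- function(pars, cfg, fwd, dlogits) {
  H <- cfg$hidden
  iz <- 1:H; ir <- (H + 1):(2 * H); in_ <- (2 * H + 1):(3 * H)
  U <- pars[["gru.U"]]; Wh <- pars[["gru.Wh"]]
  grads <- list(
    "gru.U" = U * 0, "gru.Wh" = Wh * 0, "gru.b" = numeric(3 * H),
    "dense.W" = crossprod(fwd$h, dlogits),
    "dense.b" = colSums(dlogits)
  )
  dh <- dlogits %*% t(pars[["dense.W"]])
  for (t in rev(seq_along(fwd$caches))) {
    cc <- fwd$caches[[t]]
    dz <- dh * (cc$n - cc$h_prev)
    dn <- dh * cc$z
    dh_prev <- dh * (1 - cc$z)
    dgn <- dn * (1 - cc$n^2)
    dr <- dgn * cc$ghn
    dgz <- dz * cc$z * (1 - cc$z)
    dgr <- dr * cc$r * (1 - cc$r)
    G <- cbind(dgz, dgr, dgn)
    grads[["gru.U"]] <- grads[["gru.U"]] + crossprod(cc$xt, G)
    grads[["gru.b"]] <- grads[["gru.b"]] + colSums(G)
    grads[["gru.Wh"]][, iz] <- grads[["gru.Wh"]][, iz] + crossprod(cc$h_prev, dgz)
    grads[["gru.Wh"]][, ir] <- grads[["gru.Wh"]][, ir] + crossprod(cc$h_prev, dgr)
    grads[["gru.Wh"]][, in_] <- grads[["gru.Wh"]][, in_] +
      crossprod(cc$h_prev, cc$r * dgn)
    dh <- dh_prev +
      dgz %*% t(Wh[, iz]) + dgr %*% t(Wh[, ir]) + (dgn * cc$r) %*% t(Wh[, in_])
  }
  grads
}

# ---- shared loss ------------------------------------------------------

softmax_xent <- function(logits, y01) {
  p <- softmax_rows(logits)
  B <- nrow(logits)
  eps <- 1e-12
  loss <- -mean(log(p[cbind(seq_len(B), y01 + 1L)] + eps))
  Y <- matrix(0, B, 2)
  Y[cbind(seq_len(B), y01 + 1L)] <- 1
  list(loss = loss, dlogits = (p - Y) / B, p = p)
}

nn_forward <- function(arch, pars, X, cfg, want_cache = FALSE) {
  if (arch == "cnn") cnn_forward(pars, X, cfg, want_cache)
  else gru_forward(pars, X, cfg, want_cache)
}

nn_backward <- function(arch, pars, cfg, fwd, dlogits) {
  if (arch == "cnn") cnn_backward(pars, cfg, fwd, dlogits)
  else gru_backward(pars, cfg, fwd, dlogits)
}

n_parameters <- function(pars) sum(vapply(pars, length, integer(1)))
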