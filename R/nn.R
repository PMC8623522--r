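# Minimal neural-network engine: 1-D convolutions over the window axis
# (im2col), a bidirectional tanh recurrent cell with truncated lookback,
# Adam, and patience-based early stopping. Everything is plain vectorized
# matrix algebra so training runs on one CPU with no external framework.

relu <- function(x) pmax(x, 0)

# A: N x P x C -> (N*Pout) x (k*C); rows are grouped by output position
# (block q holds all N samples), columns by (kernel offset, channel)
im2col <- function(A, k) {
  d <- dim(A)
  N <- d[1]; P <- d[2]; C <- d[3]
  Pout <- P - k + 1L
  out <- matrix(0, nrow = N * Pout, ncol = k * C)
  for (q in seq_len(Pout))
    out[(q - 1L) * N + seq_len(N), ] <-
      matrix(A[, q:(q + k - 1L), , drop = FALSE], N, k * C)
  out
}

# scatter-add the gradient of im2col back onto the input array
col2im <- function(dX, N, P, C, k) {
  Pout <- P - k + 1L
  dA <- array(0, dim = c(N, P, C))
  for (q in seq_len(Pout)) {
    blk <- array(dX[(q - 1L) * N + seq_len(N), , drop = FALSE],
                 dim = c(N, k, C))
    dA[, q:(q + k - 1L), ] <- dA[, q:(q + k - 1L), ] + blk
  }
  dA
}

he_init <- function(nr, nc) {
  matrix(stats::rnorm(nr * nc, sd = sqrt(2 / nr)), nr, nc)
}

# ---- compartment CNN -------------------------------------------------

cnn_init <- function(n_pos, n_feat, channels = c(32L, 16L), kernel = 3L) {
  list(W1 = he_init(kernel * n_feat, channels[1]),
       b1 = numeric(channels[1]),
       W2 = he_init(kernel * channels[1], channels[2]),
       b2 = numeric(channels[2]),
       W3 = he_init(channels[2], 1L) * 0.5,
       b3 = 0,
       n_pos = n_pos, n_feat = n_feat,
       channels = channels, kernel = kernel)
}

cnn_forward <- function(par, X, cache = FALSE) {
  N <- nrow(X)
  k <- par$kernel
  A0 <- array(X, dim = c(N, par$n_pos, par$n_feat))
  X1 <- im2col(A0, k)
  Z1 <- sweep(X1 %*% par$W1, 2, par$b1, `+`)
  H1 <- relu(Z1)
  P1 <- par$n_pos - k + 1L
  A1 <- array(H1, dim = c(N, P1, par$channels[1]))
  X2 <- im2col(A1, k)
  Z2 <- sweep(X2 %*% par$W2, 2, par$b2, `+`)
  H2 <- relu(Z2)
  P2 <- P1 - k + 1L
  pool <- matrix(0, N, par$channels[2])
  for (q in seq_len(P2)) pool <- pool + H2[(q - 1L) * N + seq_len(N), ,
                                           drop = FALSE]
  pool <- pool / P2
  z <- as.vector(pool %*% par$W3) + par$b3
  p <- sigmoid(z)
  if (!cache) return(p)
  list(p = p, z = z, pool = pool, H2 = H2, Z2 = Z2, X2 = X2,
       H1 = H1, Z1 = Z1, X1 = X1, N = N, P1 = P1, P2 = P2)
}

cnn_backward <- function(par, fw, y) {
  N <- fw$N
  dz <- (fw$p - y) / N                       # BCE + sigmoid
  db3 <- sum(dz)
  dW3 <- t(fw$pool) %*% dz
  dpool <- dz %*% t(par$W3)                  # N x C2
  dH2 <- dpool[rep(seq_len(N), fw$P2), , drop = FALSE] / fw$P2
  dH2 <- dH2 * (fw$Z2 > 0)
  dW2 <- t(fw$X2) %*% dH2
  db2 <- colSums(dH2)
  dX2 <- dH2 %*% t(par$W2)
  dA1 <- col2im(dX2, N, fw$P1, par$channels[1], par$kernel)
  dH1 <- matrix(dA1, N * fw$P1, par$channels[1])
  dH1 <- dH1 * (fw$Z1 > 0)
  dW1 <- t(fw$X1) %*% dH1
  db1 <- colSums(dH1)
  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2, W3 = dW3, b3 = db3)
}

# ---- bidirectional truncated recurrent smoother ----------------------

rnn_init <- function(n_in, hidden = 8L, lookback = 12L) {
  sd_x <- sqrt(1 / n_in); sd_h <- sqrt(1 / hidden)
  list(Wxf = matrix(stats::rnorm(n_in * hidden, sd = sd_x), n_in, hidden),
       Whf = matrix(stats::rnorm(hidden^2, sd = sd_h), hidden, hidden),
       bf = numeric(hidden),
       Wxb = matrix(stats::rnorm(n_in * hidden, sd = sd_x), n_in, hidden),
       Whb = matrix(stats::rnorm(hidden^2, sd = sd_h), hidden, hidden),
       bb = numeric(hidden),
       Wo = matrix(stats::rnorm(2 * hidden, sd = sd_h), 2 * hidden, 1L),
       bo = 0,
       n_in = n_in, hidden = hidden, lookback = lookback)
}

# run one direction over a N x T x D tensor, returning all hidden states
rnn_run <- function(X, Wx, Wh, b) {
  d <- dim(X)
  N <- d[1]; T <- d[2]
  H <- ncol(Wx)
  hs <- vector("list", T + 1L)
  hs[[1]] <- matrix(0, N, H)
  for (t in seq_len(T)) {
    Xt <- matrix(X[, t, , drop = FALSE], N, d[3])
    hs[[t + 1L]] <- tanh(sweep(Xt %*% Wx + hs[[t]] %*% Wh, 2, b, `+`))
  }
  hs
}

rnn_forward <- function(par, Xf, Xb, cache = FALSE) {
  hf <- rnn_run(Xf, par$Wxf, par$Whf, par$bf)
  hb <- rnn_run(Xb, par$Wxb, par$Whb, par$bb)
  Tn <- dim(Xf)[2]
  Hcat <- cbind(hf[[Tn + 1L]], hb[[Tn + 1L]])
  z <- as.vector(Hcat %*% par$Wo) + par$bo
  p <- sigmoid(z)
  if (!cache) return(p)
  list(p = p, hf = hf, hb = hb, Hcat = Hcat)
}

rnn_bptt_dir <- function(X, hs, Wx, Wh, dlast) {
  d <- dim(X)
  N <- d[1]; T <- d[2]; D <- d[3]
  dWx <- matrix(0, nrow(Wx), ncol(Wx))
  dWh <- matrix(0, nrow(Wh), ncol(Wh))
  db <- numeric(ncol(Wx))
  dh <- dlast
  for (t in rev(seq_len(T))) {
    dpre <- dh * (1 - hs[[t + 1L]]^2)
    Xt <- matrix(X[, t, , drop = FALSE], N, D)
    dWx <- dWx + t(Xt) %*% dpre
    dWh <- dWh + t(hs[[t]]) %*% dpre
    db <- db + colSums(dpre)
    dh <- dpre %*% t(Wh)
  }
  list(dWx = dWx, dWh = dWh, db = db)
}

rnn_backward <- function(par, fw, Xf, Xb, y) {
  N <- length(y)
  H <- par$hidden
  dz <- (fw$p - y) / N
  dWo <- t(fw$Hcat) %*% dz
  dbo <- sum(dz)
  dH <- dz %*% t(par$Wo)
  gf <- rnn_bptt_dir(Xf, fw$hf, par$Wxf, par$Whf,
                     dH[, seq_len(H), drop = FALSE])
  gb <- rnn_bptt_dir(Xb, fw$hb, par$Wxb, par$Whb,
                     dH[, H + seq_len(H), drop = FALSE])
  list(Wxf = gf$dWx, Whf = gf$dWh, bf = gf$db,
       Wxb = gb$dWx, Whb = gb$dWh, bb = gb$db,
       Wo = dWo, bo = dbo)
}

# ---- optimiser and early stopping ------------------------------------

PARAM_NAMES <- list(
  cnn = c("W1", "b1", "W2", "b2", "W3", "b3"),
  rnn = c("Wxf", "Whf", "bf", "Wxb", "Whb", "bb", "Wo", "bo"))

adam_init <- function(par, names) {
  list(m = lapply(par[names], function(x) x * 0),
       v = lapply(par[names], function(x) x * 0),
       t = 0L)
}

adam_step <- function(par, grads, state, names, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    par[[nm]] <- par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(par = par, state = state)
}

bce_loss <- function(p, y, eps = 1e-7) {
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Early-stopping epoch under a patience rule
#'
#' Given a per-epoch validation-loss history, returns the epoch at which
#' training stops (the first epoch lying `patience` epochs after the
#' best-so-far loss, or the last epoch) and the best epoch whose weights
#' are restored.
#'
#' @param val_losses Numeric vector of validation losses, one per epoch.
#' @param patience Number of consecutive non-improving epochs tolerated.
#' @param min_delta Minimum decrease that counts as an improvement.
#' @return List with `stop_epoch` and `best_epoch`.
#' @export
early_stop_epoch <- function(val_losses, patience = 10L, min_delta = 0) {
  best <- 1L
  for (e in seq_along(val_losses)) {
    if (val_losses[e] < val_losses[best] - min_delta) best <- e
    if (e - best >= patience)
      return(list(stop_epoch = e, best_epoch = best))
  }
  list(stop_epoch = length(val_losses), best_epoch = best)
}

# shared minibatch training loop; forward/backward are closures over the
# architecture (cnn_* or rnn_*)
train_loop <- function(par, names, n_train, batch_fn, val_loss_fn,
                       config) {
  state <- adam_init(par, names)
  history <- numeric(0)
  best_par <- par
  best <- 0L
  for (epoch in seq_len(config$max_epochs)) {
    idx <- sample.int(n_train)
    starts <- seq(1L, n_train, by = config$batch_size)
    for (s in starts) {
      b <- idx[s:min(s + config$batch_size - 1L, n_train)]
      fb <- batch_fn(par, b)
      upd <- adam_step(par, fb, state, names, lr = config$lr)
      par <- upd$par
      state <- upd$state
    }
    history <- c(history, val_loss_fn(par))
    es <- early_stop_epoch(history, config$patience, config$min_delta)
    if (es$best_epoch == epoch) best_par <- par
    best <- es$best_epoch
    if (epoch - best >= config$patience) break
  }
  list(par = best_par, history = history, best_epoch = best)
}
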