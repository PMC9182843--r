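# Batched 1-D network primitives.
#
# A batch of B equal-length signals is stored as one (B*L) x C matrix, window
# rows contiguous. Convolution is im2col + one BLAS matmul; kernels use the
# cross-correlation convention (no flip). All backward passes are exact
# gradients of the forward code.

# Zero-pad every window of X (B windows of L rows) by pl rows left, pr right.
pad_windows <- function(X, B, L, pl, pr) {
  if (pl == 0L && pr == 0L) return(list(X = X, Lp = L, tgt = NULL))
  Lp <- L + pl + pr
  tgt <- rep((0:(B - 1L)) * Lp, each = L) + pl + rep(seq_len(L), B)
  Xp <- matrix(0, nrow = B * Lp, ncol = ncol(X))
  Xp[tgt, ] <- X
  list(X = Xp, Lp = Lp, tgt = tgt)
}

conv_out_length <- function(L, kernel, stride, padding) {
  if (padding == "same") as.integer(ceiling(L / stride))
  else as.integer((L - kernel) %/% stride + 1L)
}

# Forward 1-D convolution. W: (kernel * C_in) x C_out, rows ordered offset-major
# (offset j block holds the C_in channels at kernel position j). Returns the
# (B*P) x C_out output plus a cache for the backward pass.
conv1d_forward <- function(X, B, L, W, b, kernel, stride = 1L,
                           padding = c("valid", "same")) {
  padding <- match.arg(padding)
  C_in <- ncol(X)
  if (nrow(W) != kernel * C_in) {
    stop_shape("conv weight expects %d rows (kernel %d x %d channels), got %d",
               kernel * C_in, kernel, C_in, nrow(W))
  }
  pl <- 0L; pr <- 0L
  P <- conv_out_length(L, kernel, stride, padding)
  if (padding == "same") {
    total <- max(0L, (P - 1L) * stride + kernel - L)
    pl <- total %/% 2L
    pr <- total - pl
  } else if (L < kernel) {
    stop_shape("input length %d shorter than kernel %d", L, kernel)
  }
  pad <- pad_windows(X, B, L, pl, pr)
  Lp <- pad$Lp
  base <- rep((0:(B - 1L)) * Lp, each = P) +
    rep((0:(P - 1L)) * stride, times = B)
  Xcol <- do.call(cbind, lapply(seq_len(kernel), function(j) {
    pad$X[base + j, , drop = FALSE]
  }))
  out <- Xcol %*% W
  out <- out + rep(b, each = nrow(out))
  list(out = out, P = P,
       cache = list(Xcol = Xcol, base = base, W = W, B = B, L = L, Lp = Lp,
                    P = P, kernel = kernel, C_in = C_in, tgt = pad$tgt))
}

conv1d_backward <- function(dOut, cache) {
  k <- cache$kernel; C_in <- cache$C_in
  dW <- crossprod(cache$Xcol, dOut)
  db <- colSums(dOut)
  dXcol <- dOut %*% t(cache$W)
  dXp <- matrix(0, nrow = cache$B * cache$Lp, ncol = C_in)
  for (j in seq_len(k)) {
    rows <- cache$base + j
    dXp[rows, ] <- dXp[rows, ] + dXcol[, ((j - 1L) * C_in + 1L):(j * C_in),
                                       drop = FALSE]
  }
  dX <- if (is.null(cache$tgt)) dXp else dXp[cache$tgt, , drop = FALSE]
  list(dX = dX, dW = dW, db = db)
}

relu_forward <- function(X) {
  mask <- X > 0
  list(out = X * mask, cache = mask)
}

relu_backward <- function(dOut, mask) dOut * mask

# Width-2 stride-2 max pooling; an odd trailing row is dropped.
maxpool2_forward <- function(X, B, L) {
  P <- L %/% 2L
  if (P < 1L) stop_shape("input length %d too short for width-2 pooling", L)
  base <- rep((0:(B - 1L)) * L, each = P) + rep((0:(P - 1L)) * 2L, times = B)
  r1 <- base + 1L; r2 <- base + 2L
  X1 <- X[r1, , drop = FALSE]; X2 <- X[r2, , drop = FALSE]
  m1 <- X1 >= X2
  list(out = pmax(X1, X2), P = P,
       cache = list(r1 = r1, r2 = r2, m1 = m1, n_rows = B * L, C = ncol(X)))
}

maxpool2_backward <- function(dOut, cache) {
  dX <- matrix(0, nrow = cache$n_rows, ncol = cache$C)
  dX[cache$r1, ] <- dOut * cache$m1
  dX[cache$r2, ] <- dOut * (!cache$m1)
  dX
}

# Inverted dropout: scaling at train time, identity at eval time.
dropout_forward <- function(X, rate, training) {
  if (!training || rate <= 0) return(list(out = X, cache = NULL))
  mask <- matrix(stats::rbinom(length(X), 1L, 1 - rate), nrow = nrow(X)) /
    (1 - rate)
  list(out = X * mask, cache = mask)
}

dropout_backward <- function(dOut, mask) {
  if (is.null(mask)) dOut else dOut * mask
}

# Row-wise stabilized softmax.
softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

# Kaiming (He) normal initialization for a fan_in x fan_out weight matrix.
kaiming_init <- function(fan_in, fan_out) {
  matrix(rnorm(fan_in * fan_out, sd = sqrt(2 / fan_in)), nrow = fan_in)
}

# ---- Adam over a flat named list of numeric arrays -------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
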