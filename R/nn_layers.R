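# Internal neural-network primitives: forward passes paired with hand-written
# backward passes (reverse-mode). Each *_fwd returns list(out, cache); each
# *_bwd takes the upstream gradient plus the cache and returns the input
# gradient and per-parameter gradients. All gradients are exact (verified
# against central finite differences in the test suite).

glorot_init <- function(fan_in, fan_out, gain = 1) {
  s <- gain * sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -s, s), fan_in, fan_out)
}

add_bias <- function(M, b) M + matrix(b, nrow(M), ncol(M), byrow = TRUE)

linear_fwd <- function(x, W, b) {
  list(out = add_bias(x %*% W, b), cache = list(x = x))
}

linear_bwd <- function(dout, cache, W) {
  list(dx = dout %*% t(W),
       dW = t(cache$x) %*% dout,
       db = colSums(dout))
}

softmax_rows <- function(M) {
  m <- apply(M, 1L, max)
  m[!is.finite(m)] <- 0          # fully masked row: avoid NaN from -Inf - -Inf
  E <- exp(M - m)
  E / pmax(rowSums(E), .Machine$double.xmin)
}

# Row-wise softmax backward: dM = (dP - rowSums(dP * P)) * P
softmax_rows_bwd <- function(dP, P) {
  (dP - rowSums(dP * P)) * P
}

LN_EPS <- 1e-5

layernorm_fwd <- function(x, gamma, beta) {
  d <- ncol(x)
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  sd <- sqrt(v + LN_EPS)
  xhat <- xc / sd
  out <- add_bias(xhat * matrix(gamma, nrow(x), d, byrow = TRUE), beta)
  list(out = out, cache = list(xhat = xhat, sd = sd, gamma = gamma))
}

layernorm_bwd <- function(dout, cache) {
  xhat <- cache$xhat
  dgamma <- colSums(dout * xhat)
  dbeta <- colSums(dout)
  dxhat <- dout * matrix(cache$gamma, nrow(dout), ncol(dout), byrow = TRUE)
  dx <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) / cache$sd
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

relu_fwd <- function(x) list(out = pmax(x, 0), cache = list(pos = x > 0))
relu_bwd <- function(dout, cache) dout * cache$pos

dropout_fwd <- function(x, rate, train) {
  if (!train || rate <= 0) return(list(out = x, cache = NULL))
  mask <- matrix((stats::runif(length(x)) > rate) / (1 - rate), nrow(x), ncol(x))
  list(out = x * mask, cache = mask)
}

dropout_bwd <- function(dout, cache) {
  if (is.null(cache)) dout else dout * cache
}

#' Scaled dot-product attention
#'
#' `Attention(Q, K, V) = softmax(Q K^T / sqrt(d_k)) V`, with the softmax taken
#' row-wise over key positions.
#'
#' @param Q query matrix, `L x d_k`.
#' @param K key matrix, `L' x d_k`.
#' @param V value matrix, `L' x d_v`.
#' @param d_k key dimension used for the `1/sqrt(d_k)` scaling
#'   (default `ncol(K)`).
#' @return `L x d_v` matrix of attended values.
#' @export
scaled_dot_attention <- function(Q, K, V, d_k = ncol(K)) {
  if (d_k <= 0) stop("d_k must be positive", call. = FALSE)
  P <- softmax_rows(Q %*% t(K) / sqrt(d_k))
  P %*% V
}

mha_init <- function(d_model) {
  list(Wq = glorot_init(d_model, d_model), bq = numeric(d_model),
       Wk = glorot_init(d_model, d_model), bk = numeric(d_model),
       Wv = glorot_init(d_model, d_model), bv = numeric(d_model),
       Wo = glorot_init(d_model, d_model), bo = numeric(d_model))
}

# Multi-head self-attention; `valid` is the number of non-padded rows.
# Padded key positions are masked out of every softmax so real positions are
# unaffected by batch padding.
mha_fwd <- function(x, p, n_heads, valid = nrow(x)) {
  d <- ncol(x)
  dk <- d %/% n_heads
  Qa <- add_bias(x %*% p$Wq, p$bq)
  Ka <- add_bias(x %*% p$Wk, p$bk)
  Va <- add_bias(x %*% p$Wv, p$bv)
  L <- nrow(x)
  concat <- matrix(0, L, d)
  heads <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    idx <- ((h - 1L) * dk + 1L):(h * dk)
    A <- Qa[, idx, drop = FALSE] %*% t(Ka[, idx, drop = FALSE]) / sqrt(dk)
    if (valid < L) A[, (valid + 1L):L] <- -Inf
    P <- softmax_rows(A)
    concat[, idx] <- P %*% Va[, idx, drop = FALSE]
    heads[[h]] <- P
  }
  out <- add_bias(concat %*% p$Wo, p$bo)
  list(out = out,
       cache = list(x = x, Qa = Qa, Ka = Ka, Va = Va, heads = heads,
                    concat = concat, n_heads = n_heads, dk = dk))
}

mha_bwd <- function(dout, cache, p) {
  x <- cache$x
  dk <- cache$dk
  dWo <- t(cache$concat) %*% dout
  dbo <- colSums(dout)
  dConcat <- dout %*% t(p$Wo)
  dQa <- dKa <- dVa <- matrix(0, nrow(x), ncol(x))
  for (h in seq_len(cache$n_heads)) {
    idx <- ((h - 1L) * dk + 1L):(h * dk)
    P <- cache$heads[[h]]
    dOh <- dConcat[, idx, drop = FALSE]
    dP <- dOh %*% t(cache$Va[, idx, drop = FALSE])
    dVa[, idx] <- t(P) %*% dOh
    dA <- softmax_rows_bwd(dP, P)
    dQa[, idx] <- dA %*% cache$Ka[, idx, drop = FALSE] / sqrt(dk)
    dKa[, idx] <- t(dA) %*% cache$Qa[, idx, drop = FALSE] / sqrt(dk)
  }
  dx <- dQa %*% t(p$Wq) + dKa %*% t(p$Wk) + dVa %*% t(p$Wv)
  list(dx = dx,
       grads = list(Wq = t(x) %*% dQa, bq = colSums(dQa),
                    Wk = t(x) %*% dKa, bk = colSums(dKa),
                    Wv = t(x) %*% dVa, bv = colSums(dVa),
                    Wo = dWo, bo = dbo))
}

ffn_init <- function(d_model, d_ff) {
  list(W1 = glorot_init(d_model, d_ff), b1 = numeric(d_ff),
       W2 = glorot_init(d_ff, d_model), b2 = numeric(d_model))
}

ffn_fwd <- function(x, p) {
  l1 <- linear_fwd(x, p$W1, p$b1)
  r <- relu_fwd(l1$out)
  l2 <- linear_fwd(r$out, p$W2, p$b2)
  list(out = l2$out, cache = list(l1 = l1$cache, r = r$cache, l2 = l2$cache))
}

ffn_bwd <- function(dout, cache, p) {
  b2 <- linear_bwd(dout, cache$l2, p$W2)
  dr <- relu_bwd(b2$dx, cache$r)
  b1 <- linear_bwd(dr, cache$l1, p$W1)
  list(dx = b1$dx,
       grads = list(W1 = b1$dW, b1 = b1$db, W2 = b2$dW, b2 = b2$db))
}

tblock_init <- function(d_model, d_ff) {
  list(mha = mha_init(d_model),
       ln1_g = rep(1, d_model), ln1_b = numeric(d_model),
       ffn = ffn_init(d_model, d_ff),
       ln2_g = rep(1, d_model), ln2_b = numeric(d_model))
}

# Post-norm encoder block: LN(x + MHA(x)) -> LN(. + FFN(.)).
tblock_fwd <- function(x, p, n_heads, valid = nrow(x), dropout = 0, train = FALSE) {
  mh <- mha_fwd(x, p$mha, n_heads, valid)
  dp1 <- dropout_fwd(mh$out, dropout, train)
  ln1 <- layernorm_fwd(x + dp1$out, p$ln1_g, p$ln1_b)
  ff <- ffn_fwd(ln1$out, p$ffn)
  dp2 <- dropout_fwd(ff$out, dropout, train)
  ln2 <- layernorm_fwd(ln1$out + dp2$out, p$ln2_g, p$ln2_b)
  list(out = ln2$out,
       cache = list(mh = mh$cache, dp1 = dp1$cache, ln1 = ln1$cache,
                    ff = ff$cache, dp2 = dp2$cache, ln2 = ln2$cache))
}

tblock_bwd <- function(dout, cache, p) {
  l2 <- layernorm_bwd(dout, cache$ln2)
  dff <- dropout_bwd(l2$dx, cache$dp2)
  fb <- ffn_bwd(dff, cache$ff, p$ffn)
  dln1 <- l2$dx + fb$dx
  l1 <- layernorm_bwd(dln1, cache$ln1)
  dmh <- dropout_bwd(l1$dx, cache$dp1)
  mb <- mha_bwd(dmh, cache$mh, p$mha)
  list(dx = l1$dx + mb$dx,
       grads = list(mha = mb$grads,
                    ln1_g = l1$dgamma, ln1_b = l1$dbeta,
                    ffn = fb$grads,
                    ln2_g = l2$dgamma, ln2_b = l2$dbeta))
}

conv_init <- function(kernel, c_in, c_out) {
  list(W = glorot_init(kernel * c_in, c_out), b = numeric(c_out))
}

# 1-D convolution along the sequence axis with symmetric zero padding
# (same-length output) followed by ReLU, via an im2col matrix.
conv1d_fwd <- function(x, p, kernel, activation = TRUE) {
  L <- nrow(x); c_in <- ncol(x)
  pad <- (kernel - 1L) %/% 2L
  xp <- rbind(matrix(0, pad, c_in), x, matrix(0, pad, c_in))
  M <- matrix(0, L, kernel * c_in)
  for (o in 0:(kernel - 1L)) {
    M[, o * c_in + seq_len(c_in)] <- xp[o + seq_len(L), , drop = FALSE]
  }
  pre <- add_bias(M %*% p$W, p$b)
  out <- if (activation) pmax(pre, 0) else pre
  list(out = out, cache = list(M = M, pos = pre > 0, L = L, c_in = c_in,
                               kernel = kernel, pad = pad,
                               activation = activation))
}

conv1d_bwd <- function(dout, cache, p) {
  dpre <- if (cache$activation) dout * cache$pos else dout
  dW <- t(cache$M) %*% dpre
  db <- colSums(dpre)
  dM <- dpre %*% t(p$W)
  L <- cache$L; c_in <- cache$c_in; pad <- cache$pad
  dxp <- matrix(0, L + 2L * pad, c_in)
  for (o in 0:(cache$kernel - 1L)) {
    dxp[o + seq_len(L), ] <- dxp[o + seq_len(L), , drop = FALSE] +
      dM[, o * c_in + seq_len(c_in), drop = FALSE]
  }
  list(dx = dxp[pad + seq_len(L), , drop = FALSE],
       grads = list(W = dW, b = db))
}

lstm_init <- function(d_in, hidden) {
  b <- numeric(4L * hidden)
  b[hidden + seq_len(hidden)] <- 1       # forget-gate bias
  list(Wx = glorot_init(d_in, 4L * hidden),
       Wh = glorot_init(hidden, 4L * hidden),
       b = b)
}

# Single-direction LSTM. Gate order in the 4h-wide blocks: input, forget,
# cell candidate, output.
lstm_fwd <- function(x, p) {
  L <- nrow(x)
  hdim <- ncol(p$Wh)
  h <- hdim %/% 4L
  XW <- add_bias(x %*% p$Wx, p$b)
  H <- matrix(0, L, h); C <- matrix(0, L, h)
  I <- matrix(0, L, h); Fg <- matrix(0, L, h)
  G <- matrix(0, L, h); O <- matrix(0, L, h); TC <- matrix(0, L, h)
  hprev <- numeric(h); cprev <- numeric(h)
  i_ix <- seq_len(h); f_ix <- h + i_ix; g_ix <- 2L * h + i_ix; o_ix <- 3L * h + i_ix
  for (t in seq_len(L)) {
    a <- XW[t, ] + as.vector(hprev %*% p$Wh)
    ig <- 1 / (1 + exp(-a[i_ix]))
    fg <- 1 / (1 + exp(-a[f_ix]))
    gg <- tanh(a[g_ix])
    og <- 1 / (1 + exp(-a[o_ix]))
    c_t <- fg * cprev + ig * gg
    tc <- tanh(c_t)
    h_t <- og * tc
    I[t, ] <- ig; Fg[t, ] <- fg; G[t, ] <- gg; O[t, ] <- og
    C[t, ] <- c_t; TC[t, ] <- tc; H[t, ] <- h_t
    hprev <- h_t; cprev <- c_t
  }
  list(out = H, cache = list(x = x, I = I, Fg = Fg, G = G, O = O, C = C,
                             TC = TC, H = H, h = h))
}

lstm_bwd <- function(dH, cache, p) {
  x <- cache$x
  L <- nrow(x); h <- cache$h
  DA <- matrix(0, L, 4L * h)
  dh_next <- numeric(h); dc_next <- numeric(h)
  i_ix <- seq_len(h); f_ix <- h + i_ix; g_ix <- 2L * h + i_ix; o_ix <- 3L * h + i_ix
  for (t in rev(seq_len(L))) {
    dh <- dH[t, ] + dh_next
    ig <- cache$I[t, ]; fg <- cache$Fg[t, ]; gg <- cache$G[t, ]
    og <- cache$O[t, ]; tc <- cache$TC[t, ]
    cprev <- if (t > 1L) cache$C[t - 1L, ] else numeric(h)
    do_ <- dh * tc
    dc <- dc_next + dh * og * (1 - tc * tc)
    di <- dc * gg
    dg <- dc * ig
    df <- dc * cprev
    da <- numeric(4L * h)
    da[i_ix] <- di * ig * (1 - ig)
    da[f_ix] <- df * fg * (1 - fg)
    da[g_ix] <- dg * (1 - gg * gg)
    da[o_ix] <- do_ * og * (1 - og)
    DA[t, ] <- da
    dh_next <- as.vector(da %*% t(p$Wh))
    dc_next <- dc * fg
  }
  Hprev <- rbind(numeric(h), cache$H[-L, , drop = FALSE])
  list(dx = DA %*% t(p$Wx),
       grads = list(Wx = t(x) %*% DA, Wh = t(Hprev) %*% DA, b = colSums(DA)))
}

# ---- parameter-tree utilities ------------------------------------------------

# Flatten a nested list of numeric arrays to one vector and back. Trees used
# for parameters and gradients always share the same skeleton.
flatten_tree <- function(tree) unlist(tree, use.names = FALSE)

unflatten_tree <- function(vec, skeleton) {
  utils::relist(vec, skeleton)
}

zeros_like_tree <- function(tree) {
  utils::relist(numeric(length(unlist(tree, use.names = FALSE))), tree)
}

adam_state_init <- function(n) list(t = 0L, m = numeric(n), v = numeric(n))

# `lr` may be a scalar or a per-coordinate vector (per-parameter-group
# learning rates; Adam steps are invariant to gradient scaling, so group
# rates must scale the step, not the gradient).
adam_step <- function(pvec, gvec, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * gvec
  state$v <- beta2 * state$v + (1 - beta2) * gvec * gvec
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  list(pvec = pvec - lr * mhat / (sqrt(vhat) + eps), state = state)
}

sgd_step <- function(pvec, gvec, state, lr) {
  state$t <- state$t + 1L
  list(pvec = pvec - lr * gvec, state = state)
}
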