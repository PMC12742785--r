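# Internal neural-network primitives: LSTM and dense layers with
# backpropagation through time, plus an Adam optimiser. Written on base R
# matrix algebra so the heavy lifting lands in BLAS; batches are stacked
# time-major ((t-1)*N + n row order) so the input projection of every LSTM
# layer is a single large matrix product. Elementwise steps avoid sweep()/
# pmax() in favour of cheaper vectorised forms: profiling showed those
# dominate otherwise.

nn_sigmoid <- function(x) 1 / (1 + exp(-x))

nn_act <- function(x, kind) {
  if (kind == "relu") x * (x > 0) else tanh(x)
}

# derivative expressed through the activation *output* (valid for relu/tanh)
nn_act_grad <- function(y, kind) {
  if (kind == "relu") (y > 0) * 1 else 1 - y * y
}

# add a bias row-vector to every row of a matrix (column-major recycling)
nn_add_bias <- function(Y, b) Y + rep(b, each = nrow(Y))

# Glorot-uniform initialisation; draws are column-major deterministic under
# the caller's RNG state.
nn_glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

nn_init_dense <- function(n_in, n_out) {
  list(W = nn_glorot(n_in, n_out), b = numeric(n_out))
}

# Gate column blocks in order i, f, g, o. Forget-gate bias starts at 1.
nn_init_lstm <- function(n_in, n_h) {
  b <- numeric(4 * n_h)
  b[(n_h + 1):(2 * n_h)] <- 1
  list(Wx = nn_glorot(n_in, 4 * n_h), Wh = nn_glorot(n_h, 4 * n_h), b = b)
}

nn_dense_forward <- function(X, p, act = NULL) {
  Y <- nn_add_bias(X %*% p$W, p$b)
  if (!is.null(act)) Y <- nn_act(Y, act)
  Y
}

# dY is the gradient at the layer *output* (post-activation when act given).
nn_dense_backward <- function(X, Y, p, dY, act = NULL) {
  if (!is.null(act)) dY <- dY * nn_act_grad(Y, act)
  list(
    dW = crossprod(X, dY),
    db = colSums(dY),
    dX = tcrossprod(dY, p$W)
  )
}

# X_stack: (N*T) x n_in matrix in time-major row order. When the input is the
# same at every step (decoder fed a repeated latent vector), pass the N x n_in
# matrix with `constant_input = TRUE`. `light = TRUE` skips the caches needed
# for backpropagation (scoring-only forward).
nn_lstm_forward <- function(X_stack, n_steps, p, act, constant_input = FALSE,
                            light = FALSE) {
  n_h <- nrow(p$Wh)
  if (constant_input) {
    N <- nrow(X_stack)
    XW_const <- nn_add_bias(X_stack %*% p$Wx, p$b)
  } else {
    N <- nrow(X_stack) / n_steps
    XW <- X_stack %*% p$Wx
    bias_m <- matrix(rep(p$b, each = N), N)
  }
  ih <- seq_len(n_h); if_ <- n_h + ih; ig <- 2 * n_h + ih; io <- 3 * n_h + ih
  H <- matrix(0, N * n_steps, n_h)
  if (!light) {
    gates <- matrix(0, N * n_steps, 4 * n_h)  # i, f, g, o (activated)
    Cmat <- matrix(0, N * n_steps, n_h)       # cell states c_t
  }
  h_prev <- matrix(0, N, n_h)
  c_prev <- matrix(0, N, n_h)
  for (t in seq_len(n_steps)) {
    rows <- ((t - 1L) * N + 1L):(t * N)
    z <- if (constant_input) XW_const + h_prev %*% p$Wh
         else XW[rows, , drop = FALSE] + h_prev %*% p$Wh + bias_m
    i <- nn_sigmoid(z[, ih, drop = FALSE])
    f <- nn_sigmoid(z[, if_, drop = FALSE])
    g <- nn_act(z[, ig, drop = FALSE], act)
    o <- nn_sigmoid(z[, io, drop = FALSE])
    c_t <- f * c_prev + i * g
    h_t <- o * nn_act(c_t, act)
    if (!light) {
      gates[rows, ih] <- i; gates[rows, if_] <- f
      gates[rows, ig] <- g; gates[rows, io] <- o
      Cmat[rows, ] <- c_t
    }
    H[rows, ] <- h_t
    h_prev <- h_t
    c_prev <- c_t
  }
  if (light) return(list(H = H, N = N, n_steps = n_steps))
  list(H = H, gates = gates, C = Cmat, N = N, n_steps = n_steps,
       act = act, constant_input = constant_input, X = X_stack)
}

# dH: (N*T) x n_h gradient on the full hidden sequence, or NULL; dh_last:
# N x n_h gradient on the final hidden state only (encoder bottleneck), or
# NULL. Returns parameter gradients and the input gradient (summed over steps
# when constant_input).
nn_lstm_backward <- function(fwd, p, dH = NULL, dh_last = NULL) {
  N <- fwd$N; n_steps <- fwd$n_steps; act <- fwd$act
  n_h <- nrow(p$Wh)
  ih <- seq_len(n_h); if_ <- n_h + ih; ig <- 2 * n_h + ih; io <- 3 * n_h + ih
  dZ <- matrix(0, N * n_steps, 4 * n_h)
  dh_next <- matrix(0, N, n_h)
  dc_next <- matrix(0, N, n_h)
  # transposed recurrent-weight blocks, so the in-loop products stay N x h
  tWh_i <- t(p$Wh[, ih, drop = FALSE]); tWh_f <- t(p$Wh[, if_, drop = FALSE])
  tWh_g <- t(p$Wh[, ig, drop = FALSE]); tWh_o <- t(p$Wh[, io, drop = FALSE])
  for (t in rev(seq_len(n_steps))) {
    rows <- ((t - 1L) * N + 1L):(t * N)
    dh <- dh_next
    if (!is.null(dH)) dh <- dh + dH[rows, , drop = FALSE]
    if (t == n_steps && !is.null(dh_last)) dh <- dh + dh_last
    i <- fwd$gates[rows, ih, drop = FALSE]
    f <- fwd$gates[rows, if_, drop = FALSE]
    g <- fwd$gates[rows, ig, drop = FALSE]
    o <- fwd$gates[rows, io, drop = FALSE]
    c_t <- fwd$C[rows, , drop = FALSE]
    c_act <- nn_act(c_t, act)
    dc <- dc_next + dh * o * nn_act_grad(c_act, act)
    c_prev <- if (t > 1L) fwd$C[rows - N, , drop = FALSE] else 0
    dzi <- dc * g * i * (1 - i)
    dzf <- dc * c_prev * f * (1 - f)
    dzg <- dc * i * nn_act_grad(g, act)
    dzo <- dh * c_act * o * (1 - o)
    dZ[rows, ih] <- dzi; dZ[rows, if_] <- dzf
    dZ[rows, ig] <- dzg; dZ[rows, io] <- dzo
    dh_next <- dzi %*% tWh_i + dzf %*% tWh_f + dzg %*% tWh_g + dzo %*% tWh_o
    dc_next <- dc * f
  }
  H_prev <- matrix(0, N * n_steps, n_h)
  if (n_steps > 1L) {
    H_prev[(N + 1L):(N * n_steps), ] <- fwd$H[1:(N * (n_steps - 1L)), , drop = FALSE]
  }
  if (fwd$constant_input) {
    dZ_sum <- matrix(0, N, 4 * n_h)
    for (t in seq_len(n_steps)) {
      rows <- ((t - 1L) * N + 1L):(t * N)
      dZ_sum <- dZ_sum + dZ[rows, , drop = FALSE]
    }
    dWx <- crossprod(fwd$X, dZ_sum)
    dX <- tcrossprod(dZ_sum, p$Wx)
  } else {
    dWx <- crossprod(fwd$X, dZ)
    dX <- tcrossprod(dZ, p$Wx)
  }
  list(dWx = dWx, dWh = crossprod(H_prev, dZ), db = colSums(dZ), dX = dX)
}

# Adam with keras-style defaults. `state` carries first/second moments and the
# step counter; parameters and gradients are parallel nested lists of
# matrices/vectors.
nn_adam_init <- function(params) {
  zeros <- function(x) {
    if (is.list(x)) lapply(x, zeros) else x * 0
  }
  list(m = zeros(params), v = zeros(params), t = 0L)
}

nn_adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                         beta2 = 0.999, eps = 1e-7) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      out_p <- p; out_m <- m; out_v <- v
      for (k in names(p)) {
        r <- upd(p[[k]], g[[k]], m[[k]], v[[k]])
        out_p[[k]] <- r$p; out_m[[k]] <- r$m; out_v[[k]] <- r$v
      }
      return(list(p = out_p, m = out_m, v = out_v))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
  r <- upd(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = t))
}
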