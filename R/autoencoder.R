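#' Specify the LSTM autoencoder architecture
#'
#' The model is a sequence-to-sequence autoencoder: the encoder runs two
#' stacked LSTM layers over the input window, keeps the final hidden state of
#' the second layer, and compresses it through two dense layers into a latent
#' vector; the decoder repeats the latent vector across the window length,
#' maps it through a per-step dense layer, runs a further LSTM over the
#' repeated sequence, and projects each step back to the input channels with
#' a linear map. Hidden layers use a rectified-linear activation (the LSTM
#' candidate/cell nonlinearity included); the output layer is linear because
#' the model is trained on z-scored data that can be negative.
#'
#' @param window_len Window length W (time steps per training sequence).
#' @param n_channels Number of input channels C.
#' @param encoder_units Hidden sizes of the two encoder LSTM layers.
#' @param dense_units Sizes of the two encoder dense layers; the last entry
#'   is the latent dimension.
#' @param decoder_dense Size of the per-step dense layer after the repeated
#'   latent vector.
#' @param decoder_units Hidden size of the decoder LSTM layer.
#' @param activation Hidden-layer activation, `"relu"` (default) or `"tanh"`.
#' @return A `model_spec` object.
#' @export
model_spec <- function(window_len, n_channels,
                       encoder_units = c(64L, 32L),
                       dense_units = c(32L, 16L),
                       decoder_dense = 32L,
                       decoder_units = 32L,
                       activation = c("relu", "tanh")) {
  activation <- match.arg(activation)
  window_len <- as.integer(window_len)
  n_channels <- as.integer(n_channels)
  if (length(window_len) != 1L || is.na(window_len) || window_len <= 0L)
    stop("invalid model spec: window_len must be a positive integer")
  if (length(n_channels) != 1L || is.na(n_channels) || n_channels <= 0L)
    stop("invalid model spec: n_channels must be a positive integer")
  if (length(encoder_units) != 2L || any(encoder_units <= 0))
    stop("invalid model spec: encoder_units must be two positive sizes")
  if (length(dense_units) != 2L || any(dense_units <= 0))
    stop("invalid model spec: dense_units must be two positive sizes")
  if (decoder_dense <= 0 || decoder_units <= 0)
    stop("invalid model spec: decoder sizes must be positive")
  structure(
    list(
      window_len = window_len, n_channels = n_channels,
      encoder_units = as.integer(encoder_units),
      dense_units = as.integer(dense_units),
      latent_dim = as.integer(dense_units[2L]),
      decoder_dense = as.integer(decoder_dense),
      decoder_units = as.integer(decoder_units),
      activation = activation
    ),
    class = "model_spec"
  )
}

#' Training configuration for the autoencoder
#'
#' @param epochs Number of full passes over the training windows.
#' @param batch_size Mini-batch size in windows.
#' @param learning_rate Adam learning rate.
#' @param validation_fraction Fraction of windows held out for validation
#'   (strictly between 0 and 1).
#' @param split_by Validation split unit: `"window"` draws a random fraction
#'   of windows, `"subject"` holds out whole subjects (leakage-free but
#'   coarser at small n).
#' @param seed Integer seed controlling the validation split and the epoch
#'   shuffling.
#' @return A `train_config` object.
#' @export
train_config <- function(epochs = 200L, batch_size = 1024L,
                         learning_rate = 1e-3, validation_fraction = 0.2,
                         split_by = c("window", "subject"), seed = 1L) {
  split_by <- match.arg(split_by)
  epochs <- as.integer(epochs)
  if (length(epochs) != 1L || is.na(epochs) || epochs < 1L)
    stop("invalid training config: epochs must be >= 1")
  if (batch_size < 1L) stop("invalid training config: batch_size must be >= 1")
  if (!(validation_fraction > 0 && validation_fraction < 1))
    stop("invalid training config: validation_fraction must be in (0, 1)")
  if (learning_rate <= 0) stop("invalid training config: learning_rate must be > 0")
  structure(
    list(epochs = epochs, batch_size = as.integer(batch_size),
         learning_rate = learning_rate,
         validation_fraction = validation_fraction,
         split_by = split_by, seed = as.integer(seed)),
    class = "train_config"
  )
}

ae_init_params <- function(spec) {
  C <- spec$n_channels
  e <- spec$encoder_units; d <- spec$dense_units
  list(
    e1 = nn_init_lstm(C, e[1L]),
    e2 = nn_init_lstm(e[1L], e[2L]),
    d1 = nn_init_dense(e[2L], d[1L]),
    d2 = nn_init_dense(d[1L], d[2L]),
    dd = nn_init_dense(d[2L], spec$decoder_dense),
    dl = nn_init_lstm(spec$decoder_dense, spec$decoder_units),
    out = nn_init_dense(spec$decoder_units, C)
  )
}

# Forward pass on a time-major stacked batch ((t-1)*N + n row order).
ae_forward <- function(params, X_stack, N, spec, keep_cache = FALSE) {
  Tn <- spec$window_len; act <- spec$activation
  light <- !keep_cache
  f1 <- nn_lstm_forward(X_stack, Tn, params$e1, act, light = light)
  f2 <- nn_lstm_forward(f1$H, Tn, params$e2, act, light = light)
  hT <- f2$H[((Tn - 1L) * N + 1L):(Tn * N), , drop = FALSE]
  D1 <- nn_dense_forward(hT, params$d1, act)
  LAT <- nn_dense_forward(D1, params$d2, act)
  DD <- nn_dense_forward(LAT, params$dd, act)
  f3 <- nn_lstm_forward(DD, Tn, params$dl, act, constant_input = TRUE,
                        light = light)
  Y <- nn_dense_forward(f3$H, params$out)
  if (keep_cache) {
    list(Y = Y, f1 = f1, f2 = f2, hT = hT, D1 = D1, LAT = LAT, DD = DD, f3 = f3)
  } else {
    list(Y = Y, latent = LAT)
  }
}

ae_backward <- function(params, fwd, dY, N, spec) {
  act <- spec$activation
  g_out <- nn_dense_backward(fwd$f3$H, fwd$Y, params$out, dY)
  g3 <- nn_lstm_backward(fwd$f3, params$dl, dH = g_out$dX)
  g_dd <- nn_dense_backward(fwd$LAT, fwd$DD, params$dd, g3$dX, act)
  g_d2 <- nn_dense_backward(fwd$D1, fwd$LAT, params$d2, g_dd$dX, act)
  g_d1 <- nn_dense_backward(fwd$hT, fwd$D1, params$d1, g_d2$dX, act)
  g2 <- nn_lstm_backward(fwd$f2, params$e2, dh_last = g_d1$dX)
  g1 <- nn_lstm_backward(fwd$f1, params$e1, dH = g2$dX)
  list(
    e1 = list(Wx = g1$dWx, Wh = g1$dWh, b = g1$db),
    e2 = list(Wx = g2$dWx, Wh = g2$dWh, b = g2$db),
    d1 = list(W = g_d1$dW, b = g_d1$db),
    d2 = list(W = g_d2$dW, b = g_d2$db),
    dd = list(W = g_dd$dW, b = g_dd$db),
    dl = list(Wx = g3$dWx, Wh = g3$dWh, b = g3$db),
    out = list(W = g_out$dW, b = g_out$db)
  )
}

# windows array [n, W, C] -> time-major stacked matrix (n*W) x C
ae_stack <- function(x) {
  d <- dim(x)
  matrix(x, d[1L] * d[2L], d[3L])
}

#' Build an untrained LSTM autoencoder
#'
#' Weights are initialised with Glorot-uniform draws (forget-gate biases start
#' at 1), deterministically under `seed`. The returned handle holds its
#' parameters in an environment, so training updates it in place.
#'
#' @param spec A [model_spec()].
#' @param seed Integer seed for weight initialisation.
#' @return An object of class `lstm_ae`.
#' @export
build_autoencoder <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "model_spec"))
  env <- new.env(parent = emptyenv())
  env$params <- withr::with_seed(as.integer(seed), ae_init_params(spec))
  env$trained <- FALSE
  env$history <- NULL
  env$val_idx <- NULL
  structure(list(spec = spec, seed = as.integer(seed), env = env),
            class = "lstm_ae")
}

#' @export
print.lstm_ae <- function(x, ...) {
  s <- x$spec
  cat("<lstm_ae> window", s$window_len, "x", s$n_channels, "channels |",
      "encoder LSTM", paste(s$encoder_units, collapse = "/"),
      "-> dense", paste(s$dense_units, collapse = "/"),
      "| decoder dense", s$decoder_dense, "-> LSTM", s$decoder_units,
      "| activation", s$activation,
      if (x$env$trained) "| trained" else "| untrained", "\n")
  invisible(x)
}

ae_check_windows <- function(handle, windows) {
  d <- dim(windows$data)
  if (d[2L] != handle$spec$window_len)
    stop("window length ", d[2L], " does not match model window_len ",
         handle$spec$window_len)
  if (d[3L] != handle$spec$n_channels)
    stop("channel count ", d[3L], " does not match model n_channels ",
         handle$spec$n_channels)
  invisible(TRUE)
}

#' Train the autoencoder on sliding windows
#'
#' Minimises mean squared reconstruction error with Adam. By default the
#' windows must all come from the reference (`score`) task — the whole
#' analysis rests on the model learning only the reference dynamics — and a
#' random `validation_fraction` of windows (or whole subjects, see
#' [train_config()]) is held out to track generalisation.
#'
#' @param handle An `lstm_ae` from [build_autoencoder()].
#' @param windows A `window_tensor` from [sliding_windows()].
#' @param cfg A [train_config()].
#' @param allow_mixed_tasks Set `TRUE` to bypass the reference-task guard.
#' @return A data frame with columns `epoch`, `train_loss`, `val_loss`
#'   (the training history). The handle is updated in place.
#' @export
train_autoencoder <- function(handle, windows, cfg = train_config(),
                              allow_mixed_tasks = FALSE) {
  stopifnot(inherits(handle, "lstm_ae"), inherits(cfg, "train_config"))
  ae_check_windows(handle, windows)
  if (!allow_mixed_tasks && !all(windows$provenance$task == "score")) {
    bad <- unique(windows$provenance$task)
    stop("training windows must come from the score task (found: ",
         paste(bad, collapse = ", "),
         "); pass allow_mixed_tasks = TRUE to override")
  }
  n <- dim(windows$data)[1L]
  spec <- handle$spec
  params <- handle$env$params
  opt <- nn_adam_init(params)
  history <- matrix(NA_real_, cfg$epochs, 2L)
  withr::with_seed(cfg$seed, {
    if (cfg$split_by == "subject") {
      subjects <- unique(windows$provenance$subject_id)
      n_val_s <- max(1L, floor(cfg$validation_fraction * length(subjects)))
      val_subjects <- sample(subjects, n_val_s)
      val_idx <- which(windows$provenance$subject_id %in% val_subjects)
    } else {
      val_idx <- sample.int(n, max(1L, floor(cfg$validation_fraction * n)))
    }
    train_idx <- setdiff(seq_len(n), val_idx)
    if (length(train_idx) == 0L) stop("validation split left no training windows")
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample(train_idx)
      loss_sum <- 0
      for (b_start in seq(1L, length(ord), by = cfg$batch_size)) {
        idx <- ord[b_start:min(b_start + cfg$batch_size - 1L, length(ord))]
        Nb <- length(idx)
        Xb <- ae_stack(windows$data[idx, , , drop = FALSE])
        fwd <- ae_forward(params, Xb, Nb, spec, keep_cache = TRUE)
        res <- fwd$Y - Xb
        loss_sum <- loss_sum + mean(res^2) * Nb
        dY <- res * (2 / length(res))
        grads <- ae_backward(params, fwd, dY, Nb, spec)
        st <- nn_adam_step(params, grads, opt, lr = cfg$learning_rate)
        params <- st$params
        opt <- st$state
      }
      history[ep, 1L] <- loss_sum / length(ord)
      history[ep, 2L] <- ae_eval_loss(params, windows, val_idx, spec,
                                      cfg$batch_size)
    }
  })
  handle$env$params <- params
  handle$env$trained <- TRUE
  handle$env$val_idx <- val_idx
  hist_df <- data.frame(epoch = seq_len(cfg$epochs),
                        train_loss = history[, 1L], val_loss = history[, 2L])
  handle$env$history <- hist_df
  hist_df
}

ae_eval_loss <- function(params, windows, idx, spec, batch_size) {
  total <- 0
  n_elem <- 0
  for (b_start in seq(1L, length(idx), by = batch_size)) {
    sub <- idx[b_start:min(b_start + batch_size - 1L, length(idx))]
    Xb <- ae_stack(windows$data[sub, , , drop = FALSE])
    fwd <- ae_forward(params, Xb, length(sub), spec)
    total <- total + sum((fwd$Y - Xb)^2)
    n_elem <- n_elem + length(Xb)
  }
  total / n_elem
}

#' Reconstruct windows through the autoencoder
#'
#' @param handle A (typically trained) `lstm_ae`.
#' @param windows A `window_tensor`, or a bare array of shape
#'   `n x window_len x n_channels`.
#' @param batch_size Scoring batch size.
#' @return An array with the same shape as the input windows.
#' @export
reconstruct <- function(handle, windows, batch_size = 1024L) {
  stopifnot(inherits(handle, "lstm_ae"))
  data <- if (inherits(windows, "window_tensor")) windows$data else windows
  if (length(dim(data)) != 3L) stop("windows must be an n x W x C array")
  if (inherits(windows, "window_tensor")) ae_check_windows(handle, windows)
  n <- dim(data)[1L]
  out <- array(NA_real_, dim(data))
  params <- handle$env$params
  for (b_start in seq(1L, n, by = batch_size)) {
    idx <- b_start:min(b_start + batch_size - 1L, n)
    Xb <- ae_stack(data[idx, , , drop = FALSE])
    fwd <- ae_forward(params, Xb, length(idx), handle$spec)
    out[idx, , ] <- array(fwd$Y, c(length(idx), dim(data)[2L], dim(data)[3L]))
  }
  out
}

#' Save / load a trained autoencoder
#'
#' Checkpoints use R's native serialisation and carry the model
#' specification, weights, seed, and training history.
#'
#' @param handle An `lstm_ae`.
#' @param path Checkpoint file path (conventionally `.rds`).
#' @return `save_autoencoder` returns the path invisibly; `load_autoencoder`
#'   returns the restored `lstm_ae`.
#' @export
save_autoencoder <- function(handle, path) {
  stopifnot(inherits(handle, "lstm_ae"))
  saveRDS(list(spec = handle$spec, seed = handle$seed,
               params = handle$env$params, trained = handle$env$trained,
               history = handle$env$history, val_idx = handle$env$val_idx),
          path)
  invisible(path)
}

#' @rdname save_autoencoder
#' @export
load_autoencoder <- function(path) {
  x <- readRDS(path)
  if (!all(c("spec", "params") %in% names(x)))
    stop("not an autoencoder checkpoint: ", path)
  h <- build_autoencoder(x$spec, x$seed)
  h$env$params <- x$params
  h$env$trained <- isTRUE(x$trained)
  h$env$history <- x$history
  h$env$val_idx <- x$val_idx
  h
}

#' Export a training history as CSV
#'
#' @param history Data frame from [train_autoencoder()] (columns `epoch`,
#'   `train_loss`, `val_loss`).
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_history_csv <- function(history, path) {
  stopifnot(all(c("epoch", "train_loss", "val_loss") %in% names(history)))
  utils::write.csv(history, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Encode windows to their latent representation
#'
#' @param handle An `lstm_ae`.
#' @param windows A `window_tensor` or bare `n x W x C` array.
#' @param batch_size Scoring batch size.
#' @return An `n x latent_dim` matrix.
#' @export
encode <- function(handle, windows, batch_size = 1024L) {
  stopifnot(inherits(handle, "lstm_ae"))
  data <- if (inherits(windows, "window_tensor")) windows$data else windows
  if (length(dim(data)) != 3L) stop("windows must be an n x W x C array")
  n <- dim(data)[1L]
  out <- matrix(NA_real_, n, handle$spec$latent_dim)
  for (b_start in seq(1L, n, by = batch_size)) {
    idx <- b_start:min(b_start + batch_size - 1L, n)
    Xb <- ae_stack(data[idx, , , drop = FALSE])
    fwd <- ae_forward(handle$env$params, Xb, length(idx), handle$spec)
    out[idx, ] <- fwd$latent
  }
  out
}

#' Per-channel mean squared reconstruction error
#'
#' For each window and channel, the mean over the window's time axis of the
#' squared difference between actual and reconstructed values. Averaging the
#' returned matrix over channels gives the overall per-window mean squared
#' error over all `W x C` entries.
#'
#' @param actual,predicted Arrays of shape `n x W x C` (or single `W x C`
#'   matrices, treated as one window).
#' @return An `n x C` matrix of non-negative errors.
#' @export
channel_errors <- function(actual, predicted) {
  if (is.matrix(actual)) actual <- array(actual, c(1L, dim(actual)))
  if (is.matrix(predicted)) predicted <- array(predicted, c(1L, dim(predicted)))
  if (!identical(dim(actual), dim(predicted)))
    stop("actual and predicted must have identical shapes")
  d <- dim(actual)
  res2 <- ae_stack(actual - predicted)^2     # (n*W) x C, time-major
  sums <- rowsum(res2, group = rep(seq_len(d[1L]), d[2L]), reorder = TRUE)
  unname(as.matrix(sums) / d[2L])
}

#' Score windows by per-channel reconstruction error
#'
#' @param handle A trained `lstm_ae`.
#' @param windows A `window_tensor`.
#' @param batch_size Scoring batch size.
#' @return An `n_windows x n_channels` matrix of mean squared errors.
#' @export
reconstruction_errors <- function(handle, windows, batch_size = 1024L) {
  stopifnot(inherits(handle, "lstm_ae"), inherits(windows, "window_tensor"))
  ae_check_windows(handle, windows)
  recon <- reconstruct(handle, windows, batch_size = batch_size)
  channel_errors(windows$data, recon)
}

#' Aggregate window errors to a per-subject channel error map
#'
#' Averages the per-window, per-channel errors over each subject's windows
#' (within task), and additionally reports the grand per-channel mean across
#' subjects — the per-channel bar values of a channel-error figure.
#'
#' @param errors `n_windows x n_channels` error matrix from
#'   [reconstruction_errors()].
#' @param provenance Data frame aligned with the error rows, with columns
#'   `subject_id` and `task` (a `window_tensor$provenance` works directly).
#' @param channel_ids Channel identifiers for the error columns (default
#'   `1:n_channels`).
#' @return A `channel_error_map`: list with `subject` (subject_id, task,
#'   channel, mean_error) and `grand` (task, channel, mean_error) data frames.
#' @export
subject_channel_error <- function(errors, provenance,
                                  channel_ids = seq_len(ncol(errors))) {
  if (nrow(errors) == 0L) stop("no windows to aggregate")
  if (nrow(provenance) != nrow(errors))
    stop("provenance rows must align with error rows")
  if (length(channel_ids) != ncol(errors))
    stop("channel_ids length must match error columns")
  dt <- data.table::as.data.table(errors)
  data.table::setnames(dt, as.character(channel_ids))
  dt[, `:=`(subject_id = provenance$subject_id, task = provenance$task)]
  long <- data.table::melt(dt, id.vars = c("subject_id", "task"),
                           variable.name = "channel",
                           value.name = "error", variable.factor = FALSE)
  long[, channel := as.integer(channel)]
  subj <- long[, .(mean_error = mean(error)),
               by = .(subject_id, task, channel)]
  grand <- subj[, .(mean_error = mean(mean_error)), by = .(task, channel)]
  data.table::setorder(subj, subject_id, task, channel)
  data.table::setorder(grand, task, channel)
  structure(list(subject = as.data.frame(subj), grand = as.data.frame(grand)),
            class = "channel_error_map")
}
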