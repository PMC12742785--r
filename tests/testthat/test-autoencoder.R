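test_that("analytic gradients match directional finite differences", {
  spec <- model_spec(4L, 3L, encoder_units = c(5L, 4L),
                     dense_units = c(4L, 3L), decoder_dense = 4L,
                     decoder_units = 4L, activation = "tanh")
  params <- withr::with_seed(7, fnirsae:::ae_init_params(spec))
  N <- 6L
  X <- withr::with_seed(1, array(stats::rnorm(N * 4 * 3), c(N, 4L, 3L)))
  Xs <- fnirsae:::ae_stack(X)
  loss <- function(p) {
    fwd <- fnirsae:::ae_forward(p, Xs, N, spec)
    mean((fwd$Y - Xs)^2)
  }
  fwd <- fnirsae:::ae_forward(params, Xs, N, spec, keep_cache = TRUE)
  dY <- (fwd$Y - Xs) * (2 / length(fwd$Y))
  grads <- fnirsae:::ae_backward(params, fwd, dY, N, spec)

  dirs <- withr::with_seed(3, lapply(params, function(layer)
    lapply(layer, function(x) {
      if (is.matrix(x)) matrix(stats::rnorm(length(x)), nrow(x))
      else stats::rnorm(length(x))
    })))
  shift <- function(p, d, eps) {
    for (l in names(p)) for (w in names(p[[l]]))
      p[[l]][[w]] <- p[[l]][[w]] + eps * d[[l]][[w]]
    p
  }
  eps <- 1e-6
  numeric_dd <- (loss(shift(params, dirs, eps)) -
                   loss(shift(params, dirs, -eps))) / (2 * eps)
  analytic_dd <- sum(unlist(Map(function(g, d)
    sum(unlist(Map(function(gi, di) sum(gi * di), g, d))), grads, dirs)))
  expect_equal(numeric_dd, analytic_dd, tolerance = 1e-6)
})

test_that("the autoencoder keeps shapes and is seed-deterministic", {
  spec <- model_spec(20L, 15L)
  h1 <- build_autoencoder(spec, seed = 5)
  h2 <- build_autoencoder(spec, seed = 5)
  X <- withr::with_seed(2, array(stats::rnorm(5 * 20 * 15), c(5L, 20L, 15L)))
  r1 <- reconstruct(h1, X)
  expect_equal(dim(r1), c(5L, 20L, 15L))
  expect_identical(r1, reconstruct(h2, X))
  h3 <- build_autoencoder(spec, seed = 6)
  expect_false(identical(r1, reconstruct(h3, X)))

  expect_equal(ncol(encode(h1, X)), 16L)

  expect_error(model_spec(0L, 15L), "window_len")
  expect_error(model_spec(20L, -1L), "n_channels")
})

test_that("training learns a smooth signal, is reproducible, and is guarded", {
  # smooth multichannel sinusoid: learnable within a few epochs
  n <- 400L; C <- 3L
  t_ax <- seq_len(n) / 8
  sig <- sapply(1:C, function(c) sin(2 * pi * 0.2 * t_ax + c) +
                                 0.5 * sin(2 * pi * 0.05 * t_ax))
  sig <- sig + withr::with_seed(4, matrix(stats::rnorm(n * C, sd = 0.05), n, C))
  rec <- recording(sig, "S01", "pianist", "score", 8)
  win <- sliding_windows(rec, 16L)
  spec <- model_spec(16L, C)
  h <- build_autoencoder(spec, seed = 1)
  cfg <- train_config(epochs = 6L, batch_size = 64L, seed = 1)
  hist <- train_autoencoder(h, win, cfg)
  expect_equal(nrow(hist), 6L)
  expect_lt(utils::tail(hist$train_loss, 1), hist$train_loss[1])
  expect_true(all(is.finite(hist$val_loss)))

  h2 <- build_autoencoder(spec, seed = 1)
  hist2 <- train_autoencoder(h2, win, cfg)
  expect_equal(hist$train_loss, hist2$train_loss, tolerance = 1e-6)
  expect_equal(hist$val_loss, hist2$val_loss, tolerance = 1e-6)

  expect_error(train_config(epochs = 0L), "epochs")

  improv_rec <- rec; improv_rec$task <- "improv"
  win_improv <- sliding_windows(improv_rec, 16L)
  h3 <- build_autoencoder(spec, seed = 1)
  expect_error(train_autoencoder(h3, win_improv, cfg), "score task")
  expect_silent(invisible(
    train_autoencoder(h3, win_improv,
                      train_config(epochs = 1L, batch_size = 64L, seed = 1),
                      allow_mixed_tasks = TRUE)))

  wrong <- sliding_windows(rec, 12L)
  h4 <- build_autoencoder(spec, seed = 1)
  expect_error(train_autoencoder(h4, wrong, cfg), "window length")
})

test_that("subject-level validation split holds out whole subjects", {
  recs <- lapply(1:5, function(i)
    random_recording(120L, 2L, seed = i, subject_id = sprintf("S%02d", i)))
  win <- sliding_windows(recs, 10L, stride = 5L)
  h <- build_autoencoder(model_spec(10L, 2L), seed = 1)
  train_autoencoder(h, win,
                    train_config(epochs = 1L, batch_size = 64L,
                                 validation_fraction = 0.2,
                                 split_by = "subject", seed = 2))
  val_subjects <- unique(win$provenance$subject_id[h$env$val_idx])
  train_subjects <- unique(win$provenance$subject_id[-h$env$val_idx])
  expect_length(intersect(val_subjects, train_subjects), 0L)
})

test_that("checkpoints restore the trained model exactly", {
  rec <- random_recording(80L, 2L, seed = 15)
  win <- sliding_windows(rec, 10L, stride = 4L)
  h <- build_autoencoder(model_spec(10L, 2L), seed = 3)
  hist <- train_autoencoder(h, win, train_config(epochs = 2L,
                                                 batch_size = 16L, seed = 3))
  ckpt <- withr::local_tempfile(fileext = ".rds")
  save_autoencoder(h, ckpt)
  h2 <- load_autoencoder(ckpt)
  expect_identical(reconstruct(h2, win), reconstruct(h, win))
  expect_equal(h2$env$history, hist)

  csv <- withr::local_tempfile(fileext = ".csv")
  write_history_csv(hist, csv)
  expect_equal(utils::read.csv(csv)$train_loss, hist$train_loss,
               tolerance = 1e-12)
})

test_that("per-channel errors implement the mean squared residual exactly", {
  y <- array(0, c(1L, 2L, 1L)); y[1, , 1] <- c(1, 2)
  yhat <- array(0, c(1L, 2L, 1L)); yhat[1, , 1] <- c(2, 4)
  expect_equal(channel_errors(y, yhat)[1, 1], 2.5, tolerance = 1e-12)

  X <- withr::with_seed(5, array(stats::rnorm(4 * 3 * 2), c(4L, 3L, 2L)))
  expect_equal(channel_errors(X, X), matrix(0, 4L, 2L))

  # channel permutation symmetry
  Yh <- withr::with_seed(6, array(stats::rnorm(4 * 3 * 2), c(4L, 3L, 2L)))
  e <- channel_errors(X, Yh)
  e_perm <- channel_errors(X[, , 2:1, drop = FALSE], Yh[, , 2:1, drop = FALSE])
  expect_equal(e_perm, e[, 2:1], tolerance = 1e-14)

  # averaging channel errors gives the overall window MSE
  expect_equal(rowMeans(e),
               apply((X - Yh)^2, 1, mean), tolerance = 1e-12)

  expect_error(channel_errors(X, Yh[1:2, , , drop = FALSE]), "shapes")
})

test_that("subject aggregation averages windows then subjects", {
  errors <- rbind(matrix(0.2, 3, 2), matrix(c(0.1, 0.3), 2, 2, byrow = FALSE))
  errors[4:5, ] <- c(0.1, 0.1, 0.3, 0.3)
  prov <- data.frame(subject_id = c("A", "A", "A", "B", "B"),
                     task = "improv")
  m <- subject_channel_error(errors, prov, channel_ids = c(1L, 2L))
  a_vals <- m$subject$mean_error[m$subject$subject_id == "A"]
  expect_equal(a_vals, c(0.2, 0.2))
  expect_equal(m$grand$mean_error,
               c(mean(c(0.2, 0.1)), mean(c(0.2, 0.3))))

  expect_error(subject_channel_error(errors[0, , drop = FALSE],
                                     prov[0, ]), "no windows")
})
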