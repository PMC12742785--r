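#' Resample a recording to a fixed length
#'
#' Per-channel linear interpolation onto `target_len` equally spaced points
#' over the original time span. The first and last samples are preserved
#' exactly and the sampling rate is rescaled accordingly. Used to bring
#' variable-length recordings to the uniform training length (default 1800
#' samples in the pipeline).
#'
#' @param rec A [recording()] with at least 2 samples.
#' @param target_len Target number of samples (>= 2).
#' @return A [recording()] of length `target_len`.
#' @export
resample_to_length <- function(rec, target_len) {
  stopifnot(inherits(rec, "recording"))
  n <- nrow(rec$data)
  if (n < 2L) stop("cannot resample a recording with fewer than 2 samples")
  target_len <- as.integer(target_len)
  if (target_len < 2L) stop("target_len must be >= 2")
  if (target_len == n) return(rec)
  old_t <- seq_len(n) - 1L
  new_t <- seq(0, n - 1L, length.out = target_len)
  out <- apply(rec$data, 2L, function(col) {
    stats::approx(old_t, col, xout = new_t)$y
  })
  span_s <- (n - 1L) / rec$rate_hz
  new_rate <- (target_len - 1L) / span_s
  recording(out, subject_id = rec$subject_id, group = rec$group,
            task = rec$task, rate_hz = new_rate,
            channel_ids = rec$channel_ids)
}

#' Fit per-channel normalisation statistics
#'
#' Pools all time points of all provided recordings and returns the
#' per-channel mean and standard deviation (population form, so pooling a
#' duplicated recording changes nothing). In the pipeline the statistics are
#' fitted on the reference (score) task only, so that improvisation errors
#' reflect deviation from the training distribution rather than scale
#' differences.
#'
#' @param recordings A list of [recording()]s (or a single one) with
#'   identical channel sets.
#' @return A `channel_stats` object: `mean`, `sd` (per channel),
#'   `channel_ids`, and `n_recordings`.
#' @export
fit_normalizer <- function(recordings) {
  if (inherits(recordings, "recording")) recordings <- list(recordings)
  if (length(recordings) == 0L) stop("need at least one recording")
  ids <- recordings[[1L]]$channel_ids
  for (r in recordings) {
    if (!identical(r$channel_ids, ids))
      stop("recordings have inconsistent channel sets")
  }
  all_data <- do.call(rbind, lapply(recordings, `[[`, "data"))
  mu <- colMeans(all_data)
  sdv <- sqrt(colMeans(all_data^2) - mu^2)
  degenerate <- which(!(sdv > 0))
  if (length(degenerate) > 0L)
    stop("degenerate channel with zero variance: ",
         paste(sprintf("ch%02d", ids[degenerate]), collapse = ", "))
  structure(list(mean = mu, sd = sdv, channel_ids = ids,
                 n_recordings = length(recordings)),
            class = "channel_stats")
}

#' Apply (z-score) normalisation to a recording
#'
#' @param rec A [recording()].
#' @param stats A `channel_stats` from [fit_normalizer()].
#' @return The normalised [recording()].
#' @export
apply_normalizer <- function(rec, stats) {
  stopifnot(inherits(rec, "recording"), inherits(stats, "channel_stats"))
  if (!identical(rec$channel_ids, stats$channel_ids))
    stop("recording channels do not match normalizer channels")
  rec$data <- sweep(sweep(rec$data, 2L, stats$mean, "-"), 2L, stats$sd, "/")
  rec
}

#' Invert a normalisation
#'
#' `invert_normalizer(apply_normalizer(x, s), s)` recovers `x` to within
#' floating-point error.
#'
#' @inheritParams apply_normalizer
#' @return The de-normalised [recording()].
#' @export
invert_normalizer <- function(rec, stats) {
  stopifnot(inherits(rec, "recording"), inherits(stats, "channel_stats"))
  if (!identical(rec$channel_ids, stats$channel_ids))
    stop("recording channels do not match normalizer channels")
  rec$data <- sweep(sweep(rec$data, 2L, stats$sd, "*"), 2L, stats$mean, "+")
  rec
}

#' Cut recordings into sliding windows
#'
#' Extracts windows `[i, i + W)` at starts `i = 0, stride, 2*stride, ...`
#' from each recording, giving `floor((T - W)/stride) + 1` windows per
#' recording, stacked into an `n_windows x W x n_channels` array with
#' per-window provenance (subject, task, 0-based start index).
#'
#' @param recordings A list of [recording()]s (or a single one).
#' @param W Window length in samples.
#' @param stride Step between window starts (>= 1; default 1).
#' @return A `window_tensor`: `data` array, `window_len`, `stride`,
#'   `channel_ids`, and a `provenance` data frame.
#' @export
sliding_windows <- function(recordings, W, stride = 1L) {
  if (inherits(recordings, "recording")) recordings <- list(recordings)
  if (length(recordings) == 0L) stop("need at least one recording")
  W <- as.integer(W); stride <- as.integer(stride)
  if (W < 1L) stop("W must be >= 1")
  if (stride < 1L) stop("stride must be >= 1")
  ids <- recordings[[1L]]$channel_ids
  counts <- integer(length(recordings))
  for (i in seq_along(recordings)) {
    r <- recordings[[i]]
    if (!identical(r$channel_ids, ids))
      stop("recordings have inconsistent channel sets")
    Tn <- nrow(r$data)
    if (Tn < W)
      stop("recording for subject ", r$subject_id, " (", r$task, ") has ",
           Tn, " samples, shorter than window length ", W)
    counts[i] <- (Tn - W) %/% stride + 1L
  }
  total <- sum(counts)
  C <- length(ids)
  data <- array(NA_real_, c(total, W, C))
  prov <- data.frame(subject_id = character(total), task = character(total),
                     start = integer(total))
  pos <- 0L
  for (i in seq_along(recordings)) {
    r <- recordings[[i]]
    starts <- seq(0L, by = stride, length.out = counts[i])
    for (s in starts) {
      pos <- pos + 1L
      data[pos, , ] <- r$data[(s + 1L):(s + W), , drop = FALSE]
    }
    rows <- (pos - counts[i] + 1L):pos
    prov$subject_id[rows] <- r$subject_id
    prov$task[rows] <- r$task
    prov$start[rows] <- starts
  }
  structure(list(data = data, window_len = W, stride = stride,
                 channel_ids = ids, provenance = prov),
            class = "window_tensor")
}

#' @export
print.window_tensor <- function(x, ...) {
  d <- dim(x$data)
  cat("<window_tensor>", d[1L], "windows x", d[2L], "steps x", d[3L],
      "channels (stride", x$stride, ") from",
      length(unique(x$provenance$subject_id)), "subject(s)\n")
  invisible(x)
}
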