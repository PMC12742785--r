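#' Select the window size from a sweep table
#'
#' Picks the window size with the lowest mean test reconstruction error;
#' ties break to the smallest window.
#'
#' @param table Data frame with columns `window_size`, `train_error`,
#'   `test_error` (one row per candidate, replicate-averaged).
#' @return The selected window size (integer).
#' @export
select_window_size <- function(table) {
  if (is.null(table) || nrow(table) == 0L) stop("empty window sweep table")
  stopifnot(all(c("window_size", "test_error") %in% names(table)))
  if (anyDuplicated(table$window_size)) stop("window sizes must be unique")
  best <- min(table$test_error)
  as.integer(min(table$window_size[table$test_error == best]))
}

#' Pool window errors over an ROI, per subject
#'
#' For each subject, averages the per-window, per-channel errors across the
#' ROI channels, yielding one error value per window and one vector per
#' subject. By default restricted to improvisation-task windows (the scored
#' task).
#'
#' @param window_errors `n_windows x n_channels` matrix from
#'   [reconstruction_errors()].
#' @param provenance Data frame aligned with the error rows (`subject_id`,
#'   `task`).
#' @param roi_channels ROI channel ids (default 1 and 15).
#' @param channel_ids Channel ids labelling the error columns.
#' @param task Task to pool (default `"improv"`); `NULL` pools all rows.
#' @return Named list of per-subject numeric vectors.
#' @export
roi_pool <- function(window_errors, provenance, roi_channels = c(1L, 15L),
                     channel_ids = seq_len(ncol(window_errors)),
                     task = "improv") {
  if (length(roi_channels) == 0L) stop("roi_channels must be non-empty")
  cols <- match(roi_channels, channel_ids)
  if (anyNA(cols))
    stop("invalid ROI channel id(s): ",
         paste(roi_channels[is.na(cols)], collapse = ", "))
  keep <- if (is.null(task)) rep(TRUE, nrow(window_errors))
          else provenance$task == task
  errs <- rowMeans(window_errors[keep, cols, drop = FALSE])
  subj <- provenance$subject_id[keep]
  out <- split(errs, subj)
  empty <- setdiff(unique(provenance$subject_id), names(out))
  if (length(empty) > 0L && !is.null(task))
    stop("subject(s) with zero ", task, " windows: ",
         paste(empty, collapse = ", "))
  out
}

#' Robust summaries of log reconstruction error
#'
#' Natural log of `max(error, epsilon)`, then three outlier-resistant
#' location summaries: the median, a 10% trimmed mean (dropping
#' `floor(0.10 n)` observations per tail), and the 90th percentile by linear
#' interpolation between order statistics (inclusive rule, i.e. R quantile
#' type 7).
#'
#' @param errors Non-negative error vector (one subject's windows).
#' @param epsilon Guard against `log(0)` (default `1e-12`).
#' @return A `robust_summary`: list with `median_log_mse`,
#'   `trimmed_mean_log_mse`, `p90_log_mse`, and `n`.
#' @export
robust_summaries <- function(errors, epsilon = 1e-12) {
  if (length(errors) == 0L) stop("empty error vector")
  if (any(errors < 0)) stop("errors must be non-negative")
  lx <- log(pmax(errors, epsilon))
  n <- length(lx)
  k <- floor(0.10 * n)
  sorted <- sort(lx)
  trimmed <- mean(sorted[(k + 1L):(n - k)])
  structure(list(
    median_log_mse = stats::median(lx),
    trimmed_mean_log_mse = trimmed,
    p90_log_mse = unname(stats::quantile(lx, 0.9, type = 7)),
    n = n
  ), class = "robust_summary")
}

new_test_result <- function(statistic, p_value, method, n_a, n_b) {
  stopifnot(p_value >= 0, p_value <= 1)
  structure(list(statistic = unname(statistic), p_value = unname(p_value),
                 method = method, n_a = n_a, n_b = n_b),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (n = %d vs %d)\n",
              x$method, x$statistic, x$p_value, x$n_a, x$n_b))
  invisible(x)
}

#' Welch's unequal-variance t test (two-sided)
#'
#' @param a,b Numeric samples with at least 2 values each.
#' @return A `test_result` with the t statistic and two-sided p-value from
#'   the Welch–Satterthwaite t distribution.
#' @export
welch_t_test <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stop("welch_t_test needs at least 2 values per group")
  if (stats::var(a) == 0 && stats::var(b) == 0)
    stop("undefined statistic: both samples are constant")
  ht <- stats::t.test(a, b, var.equal = FALSE)
  new_test_result(ht$statistic, ht$p.value, "Welch's t-test",
                  length(a), length(b))
}

#' Mann-Whitney U test
#'
#' U counts pairs with `a_i > b_j` plus half-ties. The two-sided p-value is
#' exact (full enumeration distribution) when `n + m <= 12` and the pooled
#' data are tie-free, and a normal approximation with tie correction (no
#' continuity correction) otherwise.
#'
#' @param a,b Numeric samples (at least 1 value each).
#' @return A `test_result` with the U statistic.
#' @export
mann_whitney_test <- function(a, b) {
  if (length(a) < 1L || length(b) < 1L)
    stop("mann_whitney_test needs non-empty samples")
  n <- length(a); m <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  U <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  has_ties <- anyDuplicated(pooled) > 0L
  if (!has_ties && n + m <= 12L) {
    # exact two-sided p over the (symmetric) tie-free null distribution of U
    dist <- stats::dwilcox(0:(n * m), n, m)
    dev <- abs(0:(n * m) - n * m / 2)
    p <- sum(dist[dev >= abs(U - n * m / 2)])
  } else {
    N <- n + m
    tie_tab <- table(pooled)
    tie_term <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
    varU <- n * m / 12 * ((N + 1) - tie_term)
    if (varU <= 0) {
      p <- 1  # everything tied: no evidence either way
    } else {
      z <- (U - n * m / 2) / sqrt(varU)
      p <- 2 * stats::pnorm(-abs(z))
    }
  }
  new_test_result(U, min(p, 1), "Mann-Whitney U", n, m)
}

#' Two-sample label-permutation test
#'
#' Builds the null by reshuffling group labels over the pooled sample
#' `n_iter` times (seeded) and recomputing the statistic; the two-sided
#' p-value uses the add-one estimator
#' `(1 + #(|perm| >= |observed|)) / (n_iter + 1)`, which never returns 0.
#'
#' @param a,b Numeric samples.
#' @param statistic `"mean_diff"` (default) or `"median_diff"`.
#' @param n_iter Number of label permutations (default 10000).
#' @param seed Integer seed for the shuffles.
#' @return A `test_result` with the observed statistic.
#' @export
permutation_test <- function(a, b, statistic = c("mean_diff", "median_diff"),
                             n_iter = 10000L, seed = 1L) {
  statistic <- match.arg(statistic)
  if (n_iter < 1L) stop("n_iter must be >= 1")
  stat_fn <- if (statistic == "mean_diff") {
    function(x, y) mean(x) - mean(y)
  } else {
    function(x, y) stats::median(x) - stats::median(y)
  }
  n <- length(a)
  pooled <- c(a, b)
  obs <- stat_fn(a, b)
  exceed <- withr::with_seed(as.integer(seed), {
    count <- 0L
    for (i in seq_len(n_iter)) {
      idx <- sample.int(length(pooled), n)
      s <- stat_fn(pooled[idx], pooled[-idx])
      if (abs(s) >= abs(obs)) count <- count + 1L
    }
    count
  })
  p <- (1 + exceed) / (n_iter + 1)
  new_test_result(obs, p, paste0("permutation (", statistic, ", ",
                                 n_iter, " iter)"), n, length(b))
}

#' Cohen's d and Cliff's delta
#'
#' `d` is the mean difference over the pooled standard deviation (n-1
#' weights); Cliff's delta is the probability that a value from `a` exceeds
#' one from `b` minus the reverse, computed over all pairs.
#'
#' @param a,b Numeric samples (>= 2 each for d; >= 1 each for delta).
#' @return An `effect_sizes` list: `cohens_d`, `cliffs_delta` (`cohens_d` is
#'   `NA` with a warning when the pooled SD is zero).
#' @export
effect_sizes <- function(a, b) {
  if (length(a) < 1L || length(b) < 1L) stop("samples must be non-empty")
  gt <- sum(outer(a, b, ">"))
  lt <- sum(outer(a, b, "<"))
  delta <- (gt - lt) / (length(a) * length(b))
  d <- NA_real_
  if (length(a) >= 2L && length(b) >= 2L) {
    sp2 <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
      (length(a) + length(b) - 2)
    if (sp2 > 0) {
      d <- (mean(a) - mean(b)) / sqrt(sp2)
    } else {
      warning("pooled SD is zero; Cohen's d undefined")
    }
  }
  structure(list(cohens_d = d, cliffs_delta = delta), class = "effect_sizes")
}

#' Full group comparison on an ROI
#'
#' Pools each subject's improvisation-window errors over the ROI channels,
#' reduces each subject to the three robust log-error summaries, and for each
#' summary runs Welch's t, Mann-Whitney U, and the label-permutation test
#' (group A vs group B), with Cohen's d and Cliff's delta. No multiplicity
#' correction is applied across the 3 summaries x 3 tests; all nine results
#' are reported.
#'
#' @param window_errors `n_windows x n_channels` error matrix.
#' @param provenance Row-aligned provenance (`subject_id`, `task`).
#' @param manifest Manifest mapping subjects to groups.
#' @param roi_channels ROI channel ids (default 1 and 15).
#' @param channel_ids Channel ids labelling the error columns.
#' @param n_perm Permutation iterations (default 10000).
#' @param seed Seed for the permutation test.
#' @param task Scored task (default `"improv"`).
#' @return A `group_comparison`: per-subject summaries by group, a tests data
#'   frame (summary x method), effect sizes per summary, and the ROI.
#' @export
compare_groups <- function(window_errors, provenance, manifest,
                           roi_channels = c(1L, 15L),
                           channel_ids = seq_len(ncol(window_errors)),
                           n_perm = 10000L, seed = 1L, task = "improv") {
  vectors <- roi_pool(window_errors, provenance, roi_channels, channel_ids,
                      task = task)
  subj_group <- unique(manifest[, c("subject_id", "group")])
  grp <- subj_group$group[match(names(vectors), subj_group$subject_id)]
  if (anyNA(grp))
    stop("subject(s) missing from manifest: ",
         paste(names(vectors)[is.na(grp)], collapse = ", "))
  if (length(unique(grp)) < 2L) stop("both groups must be non-empty")
  summaries <- lapply(vectors, robust_summaries)
  summary_df <- data.frame(
    subject_id = names(vectors), group = grp,
    median_log_mse = vapply(summaries, `[[`, 0, "median_log_mse"),
    trimmed_mean_log_mse = vapply(summaries, `[[`, 0, "trimmed_mean_log_mse"),
    p90_log_mse = vapply(summaries, `[[`, 0, "p90_log_mse"),
    row.names = NULL
  )
  summary_names <- c("median_log_mse", "trimmed_mean_log_mse", "p90_log_mse")
  tests <- list()
  effects <- list()
  for (sm in summary_names) {
    va <- summary_df[[sm]][summary_df$group == "pianist"]
    vb <- summary_df[[sm]][summary_df$group == "non_pianist"]
    res <- list(
      welch = welch_t_test(va, vb),
      mann_whitney = mann_whitney_test(va, vb),
      permutation = permutation_test(va, vb, n_iter = n_perm,
                                     seed = derive_seed(seed, match(sm, summary_names)))
    )
    for (method in names(res)) {
      tests[[length(tests) + 1L]] <- data.frame(
        summary = sm, method = method,
        statistic = res[[method]]$statistic,
        p_value = res[[method]]$p_value)
    }
    effects[[sm]] <- effect_sizes(va, vb)
  }
  structure(list(
    summaries = summary_df,
    tests = do.call(rbind, tests),
    effect_sizes = effects,
    roi_channels = as.integer(roi_channels),
    n_a = sum(summary_df$group == "pianist"),
    n_b = sum(summary_df$group == "non_pianist"),
    task = task
  ), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison> ROI channels",
      paste(x$roi_channels, collapse = ", "),
      sprintf("| pianists n = %d vs non-pianists n = %d (%s task)\n",
              x$n_a, x$n_b, x$task))
  print(x$tests, row.names = FALSE)
  for (sm in names(x$effect_sizes)) {
    es <- x$effect_sizes[[sm]]
    cat(sprintf("  %s: Cohen's d = %.3f, Cliff's delta = %.3f\n",
                sm, es$cohens_d, es$cliffs_delta))
  }
  invisible(x)
}

#' Rank channels by grand-mean reconstruction error
#'
#' @param errmap A `channel_error_map` from [subject_channel_error()].
#' @param task Task to rank (default `"improv"`).
#' @return Data frame of channels sorted by descending grand-mean error
#'   (ties by ascending channel id).
#' @export
rank_channels <- function(errmap, task = "improv") {
  stopifnot(inherits(errmap, "channel_error_map"))
  g <- errmap$grand[errmap$grand$task == task, , drop = FALSE]
  if (nrow(g) == 0L) stop("no entries for task ", task)
  g <- g[order(-g$mean_error, g$channel), c("channel", "mean_error")]
  rownames(g) <- NULL
  g
}
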