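test_that("window-size selection minimises test error with smallest-W ties", {
  expect_identical(select_window_size(
    data.frame(window_size = 10L, train_error = 0.1, test_error = 0.2)), 10L)
  tie <- data.frame(window_size = c(15L, 20L, 25L),
                    train_error = c(0.5, 0.4, 0.3),
                    test_error = c(0.2, 0.2, 0.3))
  expect_identical(select_window_size(tie), 15L)
  expect_error(select_window_size(tie[0, ]), "empty")
  expect_error(select_window_size(rbind(tie, tie[1, ])), "unique")
})

test_that("ROI pooling averages channels per window and validates ids", {
  errors <- matrix(0.2, 6, 3)
  prov <- data.frame(subject_id = rep(c("A", "B"), each = 3), task = "improv")
  v <- roi_pool(errors, prov, roi_channels = 2L)
  expect_equal(v$A, rep(0.2, 3), ignore_attr = TRUE)

  errors2 <- matrix(c(0.1, 0.3), 1, 2)
  prov2 <- data.frame(subject_id = "A", task = "improv")
  expect_equal(unname(roi_pool(errors2, prov2, c(1L, 2L),
                               channel_ids = c(1L, 2L))$A), 0.2)

  expect_error(roi_pool(errors, prov, roi_channels = 99L), "invalid ROI")
  prov_mixed <- prov; prov_mixed$task[4:6] <- "score"
  expect_error(roi_pool(errors, prov_mixed, 1L), "zero improv windows")
})

test_that("robust summaries follow the stated conventions", {
  rs <- robust_summaries(rep(exp(1), 20))
  expect_equal(rs$median_log_mse, 1)
  expect_equal(rs$trimmed_mean_log_mse, 1)
  expect_equal(rs$p90_log_mse, 1)

  x <- exp(1:10)   # log-errors 1..10
  rs2 <- robust_summaries(x)
  expect_equal(rs2$trimmed_mean_log_mse, mean(2:9))  # drop 1 per tail
  expect_equal(rs2$p90_log_mse, 9.1)                 # inclusive interpolation
  expect_equal(rs2$median_log_mse, 5.5)

  # zero errors are epsilon-guarded, not -Inf
  expect_true(is.finite(robust_summaries(c(0, 1, 2))$median_log_mse))
  expect_error(robust_summaries(numeric(0)), "empty")
  expect_error(robust_summaries(c(-1, 1)), "non-negative")

  for (s in 1:20) {
    x <- withr::with_seed(s, stats::rexp(sample(5:50, 1)))
    rs <- robust_summaries(x)
    expect_lte(rs$median_log_mse, rs$p90_log_mse)
  }
})

test_that("Welch's t matches the textbook formula and its symmetry limits", {
  r <- welch_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  a <- c(1, 2, 3, 4); b <- c(2, 4, 6, 8)
  r2 <- welch_t_test(a, b)
  se <- sqrt(stats::var(a) / 4 + stats::var(b) / 4)
  expect_equal(r2$statistic, (mean(a) - mean(b)) / se, tolerance = 1e-9)
  df <- se^4 / ((stats::var(a) / 4)^2 / 3 + (stats::var(b) / 4)^2 / 3)
  expect_equal(r2$p_value, 2 * stats::pt(-abs(r2$statistic), df),
               tolerance = 1e-9)

  expect_error(welch_t_test(1, c(1, 2)), "at least 2")
  expect_error(welch_t_test(c(1, 1), c(1, 1)), "undefined")
})

test_that("Mann-Whitney U and exact p agree with full enumeration", {
  expect_equal(mann_whitney_test(c(5, 6), c(1, 2))$statistic, 4)
  expect_equal(mann_whitney_test(3, 3)$statistic, 0.5)

  r <- withr::with_seed(10, mann_whitney_test(stats::rnorm(5), stats::rnorm(4)))
  ab <- withr::with_seed(10, list(a = stats::rnorm(5), b = stats::rnorm(4)))
  expect_equal(r$p_value, enumerate_mw_p(ab$a, ab$b), tolerance = 1e-12)

  # exhaustive: every assignment of every size with n + m <= 10, tie-free
  pooled_master <- withr::with_seed(11, stats::rnorm(10))
  for (N in 4:10) {
    for (n in 2:(N - 2)) {
      pooled <- pooled_master[seq_len(N)]
      combos <- utils::combn(N, n)
      take <- seq(1, ncol(combos), length.out = min(25, ncol(combos)))
      for (ci in as.integer(take)) {
        idx <- combos[, ci]
        a <- pooled[idx]; b <- pooled[-idx]
        ours <- mann_whitney_test(a, b)
        expect_equal(ours$p_value, enumerate_mw_p(a, b), tolerance = 1e-12)
        # independent cross-check against the standard exact test
        expect_equal(ours$p_value,
                     stats::wilcox.test(a, b, exact = TRUE)$p.value,
                     tolerance = 1e-12)
      }
    }
  }

  # tied / large-sample branch agrees with the tie-corrected normal form
  a <- c(1, 2, 2, 3, 5, 5, 7); b <- c(2, 3, 3, 4, 5, 6, 8)
  ours <- mann_whitney_test(a, b)
  ref <- stats::wilcox.test(a, b, exact = FALSE, correct = FALSE)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-9)
})

test_that("permutation p-values behave as the add-one estimator demands", {
  a <- c(1, 2, 3); b <- c(3, 1, 2)
  expect_gte(permutation_test(a, b, n_iter = 500, seed = 1)$p_value, 0.99)

  p1 <- permutation_test(c(1, 2), c(10, 20), n_iter = 1, seed = 3)$p_value
  expect_true(p1 %in% c(0.5, 1))

  # monotone non-increasing in |observed| at fixed pooled data and seed
  pooled <- withr::with_seed(4, stats::rnorm(10))
  stats_obs <- c(); pvals <- c()
  for (k in 1:6) {
    idx <- withr::with_seed(k, sample(10, 5))
    a <- pooled[idx]; b <- pooled[-idx]
    stats_obs <- c(stats_obs, abs(mean(a) - mean(b)))
    pvals <- c(pvals, permutation_test(a, b, n_iter = 300, seed = 99)$p_value)
  }
  ord <- order(stats_obs)
  expect_true(all(diff(pvals[ord]) <= 1e-12))

  # approximate label-swap symmetry
  a <- withr::with_seed(5, stats::rnorm(16)); b <- withr::with_seed(6, stats::rnorm(6))
  pab <- permutation_test(a, b, n_iter = 2000, seed = 7)$p_value
  pba <- permutation_test(b, a, n_iter = 2000, seed = 7)$p_value
  expect_lt(abs(pab - pba), 0.06)

  # quick null calibration at the study's group sizes
  rej <- 0
  for (i in 1:200) {
    x <- withr::with_seed(1000 + i, stats::rnorm(22))
    p <- permutation_test(x[1:16], x[17:22], n_iter = 99,
                          seed = 2000 + i)$p_value
    rej <- rej + (p <= 0.05)
  }
  expect_gte(rej / 200, 0.01)
  expect_lte(rej / 200, 0.10)
})

test_that("effect sizes match their definitions and oracles", {
  es <- effect_sizes(c(0, 1, 2), c(-1, 0, 1))
  expect_equal(es$cohens_d, 1)

  expect_equal(effect_sizes(c(5, 6), c(1, 2))$cliffs_delta, 1)
  expect_equal(effect_sizes(c(1, 2), c(5, 6))$cliffs_delta, -1)

  for (s in 1:30) {
    ab <- withr::with_seed(s, list(a = stats::rnorm(16), b = stats::rnorm(6)))
    es <- effect_sizes(ab$a, ab$b)
    expect_equal(es$cliffs_delta, cliffs_delta_loops(ab$a, ab$b),
                 tolerance = 1e-12)
    # delta = 2U/(nm) - 1 on tie-free data
    U <- mann_whitney_test(ab$a, ab$b)$statistic
    expect_equal(es$cliffs_delta, 2 * U / (16 * 6) - 1, tolerance = 1e-12)
  }

  expect_warning(es0 <- effect_sizes(c(1, 1), c(1, 1)), "pooled SD")
  expect_true(is.na(es0$cohens_d))
  expect_equal(es0$cliffs_delta, 0)
})

test_that("group comparison is null for identical groups and assembles fully", {
  # groups identical as multisets: subject i in each group gets the same
  # scaled error vector, so group contrasts vanish but variances do not
  n_win <- 10L
  base <- seq(0.1, 1, length.out = n_win)
  scales <- c(1, 2, 3, 1, 2, 3)
  errors <- matrix(unlist(lapply(scales, function(s) s * base)), ncol = 1)
  prov <- data.frame(subject_id = rep(sprintf("S%02d", 1:6), each = n_win),
                     task = "improv")
  manifest <- memory_manifest(sprintf("S%02d", 1:6),
                              rep(c("pianist", "non_pianist"), each = 3))
  gc <- compare_groups(errors, prov, manifest, roi_channels = 1L,
                       channel_ids = 1L, n_perm = 200, seed = 1)
  expect_equal(nrow(gc$tests), 9L)
  for (es in gc$effect_sizes) {
    expect_equal(es$cliffs_delta, 0)
    expect_equal(es$cohens_d, 0)
  }
  welch_p <- gc$tests$p_value[gc$tests$method == "welch"]
  expect_true(all(abs(welch_p - 1) < 1e-12))
  expect_equal(gc$n_a, 3L)
  expect_equal(gc$n_b, 3L)
})

test_that("channel ranking orders by error with id tie-breaks", {
  errors <- matrix(0.2, 4, 15)
  prov <- data.frame(subject_id = rep(c("A", "B"), each = 2), task = "improv")
  m <- subject_channel_error(errors, prov)
  r <- rank_channels(m)
  expect_equal(r$channel, 1:15)

  errors2 <- errors; errors2[, 7] <- 0.4
  r2 <- rank_channels(subject_channel_error(errors2, prov))
  expect_equal(r2$channel[1], 7L)
})
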