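test_that("block design places the play indicator exactly", {
  d <- make_block_design(task_timing(), 8)
  expect_length(d, 1280L)
  expect_identical(which(d == 1), 561:1040)  # 0-based [560, 1040)

  d1 <- make_block_design(task_timing(1, 1, 1, 1, 1), 1)
  expect_equal(d1, c(0, 0, 0, 1, 0))

  expect_error(task_timing(play_s = 0), "invalid config")
  expect_error(make_block_design(task_timing(), -1), "invalid config")
})

test_that("hemodynamic response follows the double-gamma kernel", {
  expect_equal(hemodynamic_response(numeric(100), 8), numeric(100))

  impulse <- c(1, numeric(511))
  resp <- hemodynamic_response(impulse, 8)
  # kernel peak should sit at 6 s (sample 48, 0-based) within one sample
  expect_lte(abs(which.max(resp) - 1L - 48L), 1L)

  boxcar <- make_block_design(task_timing(), 8)
  resp_box <- hemodynamic_response(boxcar, 8)
  expect_gt(max(resp_box), max(resp))

  expect_error(hemodynamic_response(c(0, 2, 0), 8), "0/1")
})

test_that("simulated recordings are deterministic and reduce to the clean evoked signal", {
  cc <- cohort_config(seed = 5)
  r1 <- simulate_recording(cc, "pianist", "score", subject_seed = 42)
  r2 <- simulate_recording(cc, "pianist", "score", subject_seed = 42)
  expect_identical(r1$data, r2$data)
  r3 <- simulate_recording(cc, "pianist", "score", subject_seed = 43)
  expect_false(identical(r1$data, r3$data))

  # noise-free limit: each channel is a constant gain times the evoked shape
  cc0 <- cohort_config(
    seed = 5, noise = noise_params(white_sd = 0, drift_coeff = 0,
                                   osc_components = list()))
  r <- simulate_recording(cc0, "pianist", "score", subject_seed = 42)
  evoked <- hemodynamic_response(make_block_design(cc0$timing, cc0$rate_hz), 8)
  on_idx <- which(evoked > 0.5)
  for (ch in c(1L, 8L, 15L)) {
    gain <- r$data[on_idx[1], ch] / evoked[on_idx[1]]
    expect_gt(gain, 0)
    expect_equal(r$data[, ch], gain * evoked, tolerance = 1e-12)
  }
})

test_that("noise variance is close to the analytic component sum", {
  np <- noise_params(white_sd = 0.3, drift_coeff = 0,
                     osc_components = list(c(1.0, 0.10), c(0.3, 0.15),
                                           c(0.1, 0.20)))
  cc <- cohort_config(seed = 9, noise = np)
  cc0 <- cohort_config(
    seed = 9, noise = noise_params(white_sd = 0, drift_coeff = 0,
                                   osc_components = list()))
  analytic <- 0.3^2 + (0.10^2 + 0.15^2 + 0.20^2) / 2
  vars <- vapply(1:100, function(s) {
    noisy <- simulate_recording(cc, "pianist", "score", subject_seed = s)
    clean <- simulate_recording(cc0, "pianist", "score", subject_seed = s)
    mean(apply(noisy$data - clean$data, 2, stats::var))
  }, 0)
  expect_gt(mean(vars), analytic / 3)
  expect_lt(mean(vars), analytic * 3)
})

test_that("channel effect injection is local, null-safe, and raises play-block variance", {
  cc <- cohort_config(seed = 3)
  design <- make_block_design(cc$timing, cc$rate_hz)
  rec <- simulate_recording(cc, "pianist", "improv", subject_seed = 7)

  same <- inject_channel_effect(rec, null_effect(), design, seed = 1)
  expect_identical(same$data, rec$data)

  eff <- effect_spec(target_channels = 1L, burst_rate = 5, burst_amp_sd = 10,
                     variance_inflation = 2)
  out <- inject_channel_effect(rec, eff, design, seed = 1, white_sd = 0.3)
  expect_identical(out$data[, 2:15], rec$data[, 2:15])
  expect_false(identical(out$data[, 1], rec$data[, 1]))

  play <- which(design == 1)
  rest <- which(design == 0)
  # de-mean against the clean signal so only the injected part is compared
  delta <- out$data[, 1] - rec$data[, 1]
  expect_gt(stats::var(delta[play]), stats::var(delta[rest]) + 0.1)

  expect_error(
    inject_channel_effect(rec, effect_spec(target_channels = 99L), design, 1),
    "unknown channel")
})

test_that("cohorts have the right composition and are reproducible", {
  cc <- cohort_config(seed = 21)
  coh <- simulate_cohort(cc)
  expect_length(coh$recordings, 44L)
  expect_equal(length(unique(coh$manifest$subject_id)), 22L)
  expect_equal(sum(coh$manifest$group == "pianist" &
                     coh$manifest$task == "score"), 16L)
  expect_equal(sum(coh$manifest$group == "non_pianist" &
                     coh$manifest$task == "score"), 6L)

  coh2 <- simulate_cohort(cc)
  expect_identical(coh$manifest, coh2$manifest)
  expect_identical(coh$recordings[[1]]$data, coh2$recordings[[1]]$data)

  # null effect: score and improv recordings of one subject differ only by
  # their noise draws (same marginal construction, no injection)
  cc_null <- cohort_config(seed = 21, effect = null_effect())
  coh_null <- simulate_cohort(cc_null)
  imp <- coh_null$recordings[[which(coh_null$manifest$task == "improv")[1]]]
  expect_equal(stats::var(imp$data[, 1]),
               stats::var(coh_null$recordings[[1]]$data[, 1]),
               tolerance = 0.5)
})

test_that("target-channel error grows with the planted burst amplitude", {
  # train once on score windows (bursts never touch the score task), then
  # score improv cohorts that differ only in burst amplitude
  amps <- c(0, 2, 5, 10)
  base <- function(a) cohort_config(
    n_group_a = 3L, n_group_b = 2L, seed = 31,
    effect = effect_spec(burst_rate = 3, burst_amp_sd = a,
                         variance_inflation = 2))
  cohorts <- lapply(amps, function(a) simulate_cohort(base(a)))

  norm <- fit_normalizer(Filter(function(r) r$task == "score",
                                cohorts[[1]]$recordings))
  score_recs <- lapply(Filter(function(r) r$task == "score",
                              cohorts[[1]]$recordings),
                       apply_normalizer, stats = norm)
  win_score <- sliding_windows(score_recs, 20L, stride = 30L)
  handle <- build_autoencoder(model_spec(20L, 15L), seed = 1)
  train_autoencoder(handle, win_score,
                    train_config(epochs = 8L, batch_size = 64L, seed = 1))

  roi_err <- vapply(cohorts, function(coh) {
    improv <- lapply(Filter(function(r) r$task == "improv", coh$recordings),
                     apply_normalizer, stats = norm)
    win <- sliding_windows(improv, 20L, stride = 30L)
    mean(reconstruction_errors(handle, win)[, c(1L, 15L)])
  }, 0)
  expect_true(all(diff(roi_err) >= 0))
})
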