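#' Block-design task timing
#'
#' One experimental cycle: rest, preparation, rest, play, rest. The defaults
#' are the 30/30/10/60/30 s cycle (160 s total) used for every task
#' condition.
#'
#' @param rest1_s,prep_s,rest2_s,play_s,rest3_s Durations in seconds, all
#'   strictly positive.
#' @return A `task_timing` object with a `total_s` field.
#' @export
task_timing <- function(rest1_s = 30, prep_s = 30, rest2_s = 10,
                        play_s = 60, rest3_s = 30) {
  d <- c(rest1_s = rest1_s, prep_s = prep_s, rest2_s = rest2_s,
         play_s = play_s, rest3_s = rest3_s)
  if (!all(is.finite(d)) || any(d <= 0))
    stop("invalid config: all timing durations must be > 0")
  structure(c(as.list(d), list(total_s = sum(d))), class = "task_timing")
}

#' Physiological and instrumental noise parameters
#'
#' A standard fNIRS noise model: white measurement noise, per-channel linear
#' drift, and three physiological oscillations (cardiac ~1 Hz, respiratory
#' ~0.3 Hz, Mayer waves ~0.1 Hz) with phases jittered across channels.
#' Amplitudes are in the same arbitrary concentration units as the evoked
#' response (which has unit plateau gain, see [hemodynamic_response()]).
#'
#' @param white_sd White-noise standard deviation.
#' @param drift_coeff Scale of the per-channel linear drift slope, in units
#'   per second (each channel draws its slope from
#'   `Normal(0, drift_coeff)`).
#' @param osc_components List of `c(freq_hz, amplitude)` pairs.
#' @param osc_phase_jitter Per-channel phase jitter (radians, SD of a normal
#'   offset around each component's shared random phase).
#' @return A `noise_params` object.
#' @export
noise_params <- function(white_sd = 0.3, drift_coeff = 0.001,
                         osc_components = list(c(1.0, 0.10),
                                               c(0.3, 0.15),
                                               c(0.1, 0.20)),
                         osc_phase_jitter = 0.5) {
  if (white_sd < 0 || drift_coeff < 0 || osc_phase_jitter < 0)
    stop("invalid config: noise amplitudes must be >= 0")
  for (cmp in osc_components) {
    if (length(cmp) != 2L || cmp[1L] <= 0 || cmp[2L] < 0)
      stop("invalid config: oscillation components must be (freq > 0, amp >= 0)")
  }
  structure(list(white_sd = white_sd, drift_coeff = drift_coeff,
                 osc_components = osc_components,
                 osc_phase_jitter = osc_phase_jitter),
            class = "noise_params")
}

#' Planted group-by-task effect
#'
#' Operationalises "distinct neural engagement" as a recoverable anomaly:
#' during the play block of the affected task, target channels receive
#' short Gaussian-bump transients (Poisson counts per play block, width about
#' one second) and inflated white-noise variance. Detection via
#' reconstruction error responds to dynamical deviation, not to mean offsets
#' (which normalization would remove).
#'
#' @param target_channels Channel ids receiving the effect (default 1 and 15,
#'   the bilateral inferior-frontal sites of the 15-channel montage).
#' @param burst_rate Expected transient count per play block.
#' @param burst_amp_sd Transient amplitude in units of the white-noise SD.
#' @param variance_inflation Multiplier (>= 1) on white-noise variance in
#'   target channels during the play block.
#' @return An `effect_spec` object.
#' @export
effect_spec <- function(target_channels = c(1L, 15L), burst_rate = 3,
                        burst_amp_sd = 10, variance_inflation = 2) {
  if (burst_rate < 0) stop("invalid config: burst_rate must be >= 0")
  if (variance_inflation < 1)
    stop("invalid config: variance_inflation must be >= 1")
  if (burst_amp_sd < 0) stop("invalid config: burst_amp_sd must be >= 0")
  structure(list(target_channels = as.integer(target_channels),
                 burst_rate = burst_rate, burst_amp_sd = burst_amp_sd,
                 variance_inflation = variance_inflation),
            class = "effect_spec")
}

#' Null (no-op) effect specification
#' @return An `effect_spec` that leaves recordings untouched.
#' @export
null_effect <- function() {
  effect_spec(burst_rate = 0, burst_amp_sd = 0, variance_inflation = 1)
}

#' Synthetic cohort configuration
#'
#' Defaults mirror the study conditions: 16 pianists vs 6 non-pianist
#' musicians, 15 channels sampled at 8 Hz, one 160 s task cycle per
#' recording, with the planted effect applied to the pianist group's
#' improvisation recordings.
#'
#' @param n_group_a Pianist count.
#' @param n_group_b Non-pianist count.
#' @param rate_hz Sampling rate (Hz).
#' @param n_channels Number of channels.
#' @param timing A [task_timing()].
#' @param noise A [noise_params()].
#' @param effect An [effect_spec()] planted in improvisation recordings.
#' @param effect_groups Which group(s) receive the effect (default pianists
#'   only).
#' @param repeat_cycles Number of concatenated task cycles per recording.
#' @param gain_sdlog Log-SD of the per-subject, per-channel lognormal evoked
#'   gain (inter-subject variability).
#' @param seed Master seed for the cohort.
#' @return A `cohort_config` object.
#' @export
cohort_config <- function(n_group_a = 16L, n_group_b = 6L, rate_hz = 8,
                          n_channels = 15L, timing = task_timing(),
                          noise = noise_params(), effect = effect_spec(),
                          effect_groups = "pianist", repeat_cycles = 1L,
                          gain_sdlog = 0.2, seed = 1L) {
  if (n_group_a < 1L || n_group_b < 1L)
    stop("invalid config: group counts must be >= 1")
  if (rate_hz <= 0) stop("invalid config: rate_hz must be > 0")
  if (n_channels < 1L) stop("invalid config: n_channels must be >= 1")
  stopifnot(inherits(timing, "task_timing"), inherits(noise, "noise_params"),
            inherits(effect, "effect_spec"))
  nyq <- rate_hz / 2
  for (cmp in noise$osc_components) {
    if (cmp[1L] >= nyq)
      stop("invalid config: oscillation at ", cmp[1L],
           " Hz is at or above Nyquist (", nyq, " Hz)")
  }
  if (!all(effect$target_channels %in% seq_len(n_channels)))
    stop("invalid config: effect target channels outside 1..", n_channels)
  if (!all(effect_groups %in% GROUP_LEVELS))
    stop("invalid config: effect_groups must be within ",
         paste(GROUP_LEVELS, collapse = ", "))
  if (repeat_cycles < 1L) stop("invalid config: repeat_cycles must be >= 1")
  structure(list(n_group_a = as.integer(n_group_a),
                 n_group_b = as.integer(n_group_b),
                 rate_hz = rate_hz, n_channels = as.integer(n_channels),
                 timing = timing, noise = noise, effect = effect,
                 effect_groups = effect_groups,
                 repeat_cycles = as.integer(repeat_cycles),
                 gain_sdlog = gain_sdlog, seed = as.integer(seed)),
            class = "cohort_config")
}

#' Binary play-block indicator for one task cycle
#'
#' @param timing A [task_timing()].
#' @param rate_hz Sampling rate (Hz).
#' @return A 0/1 vector of length `round(total_s * rate_hz)`, 1 exactly on
#'   the play interval (half-open in seconds, 0-based samples).
#' @export
make_block_design <- function(timing, rate_hz) {
  stopifnot(inherits(timing, "task_timing"))
  if (!(is.numeric(rate_hz) && rate_hz > 0))
    stop("invalid config: rate_hz must be > 0")
  n <- round(timing$total_s * rate_hz)
  onset_s <- timing$rest1_s + timing$prep_s + timing$rest2_s
  start <- round(onset_s * rate_hz)          # 0-based, inclusive
  end <- round((onset_s + timing$play_s) * rate_hz)  # 0-based, exclusive
  design <- numeric(n)
  design[(start + 1L):min(end, n)] <- 1
  design
}

# Canonical double-gamma HRF kernel sampled at 1/rate_hz, scaled so that a
# sustained stimulus produces a plateau of height ~1 (kernel sums to 1 before
# the undershoot correction divides out).
hrf_kernel <- function(rate_hz, peak_s = 6, undershoot_s = 16,
                       undershoot_ratio = 1 / 6, length_s = 32) {
  t <- seq(0, length_s, by = 1 / rate_hz)
  k <- stats::dgamma(t, shape = peak_s + 1, rate = 1) -
    undershoot_ratio * stats::dgamma(t, shape = undershoot_s + 1, rate = 1)
  k / rate_hz / (1 - undershoot_ratio)
}

#' Task-evoked hemodynamic response
#'
#' Convolves a 0/1 stimulus indicator with a canonical double-gamma
#' hemodynamic response function (peak 6 s, undershoot 16 s, undershoot ratio
#' 1/6, 32 s kernel), truncated to the input length. The kernel is scaled so
#' a sustained stimulus plateaus at height ~1, making the channel gain the
#' evoked amplitude in concentration units.
#'
#' @param design 0/1 indicator vector, e.g. from [make_block_design()].
#' @param rate_hz Sampling rate (Hz).
#' @param peak_s,undershoot_s,undershoot_ratio,length_s HRF shape parameters.
#' @return Numeric vector of the same length as `design`.
#' @export
hemodynamic_response <- function(design, rate_hz, peak_s = 6,
                                 undershoot_s = 16, undershoot_ratio = 1 / 6,
                                 length_s = 32) {
  if (!all(design %in% c(0, 1))) stop("design must be a 0/1 indicator")
  k <- hrf_kernel(rate_hz, peak_s, undershoot_s, undershoot_ratio, length_s)
  n <- length(design)
  out <- stats::convolve(design, rev(k), type = "open")[seq_len(n)]
  # exact zeros where nothing has happened yet, despite FFT round-off
  out[abs(out) < 1e-12] <- 0
  if (all(design == 0)) out[] <- 0
  out
}

# deterministic per-subject / per-task seed derivation, kept below 2^31
derive_seed <- function(seed, a, b = 0L) {
  as.integer((as.numeric(seed) * 1009 + as.numeric(a) * 9973 +
                as.numeric(b) * 7919) %% 2147483647)
}

#' Simulate one subject's single-task recording
#'
#' Each channel is the sum of a gain-scaled evoked response (per-subject,
#' per-channel lognormal gains, shared across tasks), a linear drift, phase-
#' jittered physiological oscillations, and white noise. Deterministic given
#' the seeds.
#'
#' @param config A [cohort_config()].
#' @param group Group label for the output recording.
#' @param task Task label.
#' @param subject_seed Seed controlling the subject's gains (shared between
#'   the subject's tasks).
#' @param subject_id Subject identifier.
#' @return A [recording()] of one (or `repeat_cycles`) task cycle(s).
#' @export
simulate_recording <- function(config, group, task, subject_seed,
                               subject_id = "S01") {
  stopifnot(inherits(config, "cohort_config"))
  C <- config$n_channels
  design1 <- make_block_design(config$timing, config$rate_hz)
  design <- rep(design1, config$repeat_cycles)
  n <- length(design)
  evoked1 <- hemodynamic_response(design1, config$rate_hz)
  evoked <- rep(evoked1, config$repeat_cycles)
  gains <- withr::with_seed(derive_seed(subject_seed, 1L),
                            stats::rlnorm(C, 0, config$gain_sdlog))
  noise_seed <- derive_seed(subject_seed, 2L, match(task, TASK_LEVELS))
  np <- config$noise
  tm <- (seq_len(n) - 1L) / config$rate_hz
  data <- withr::with_seed(noise_seed, {
    m <- outer(evoked, gains)
    slopes <- stats::rnorm(C, 0, np$drift_coeff)
    m <- m + outer(tm, slopes)
    for (cmp in np$osc_components) {
      base_phase <- stats::runif(1, 0, 2 * pi)
      phases <- base_phase + stats::rnorm(C, 0, np$osc_phase_jitter)
      m <- m + cmp[2L] * sin(outer(2 * pi * cmp[1L] * tm, phases, "+"))
    }
    m + matrix(stats::rnorm(n * C, 0, np$white_sd), n, C)
  })
  recording(data, subject_id = subject_id, group = group, task = task,
            rate_hz = config$rate_hz, channel_ids = seq_len(C))
}

#' Plant the channel effect into a recording
#'
#' Within play-block samples only, target channels receive Poisson-count
#' Gaussian-bump transients (width ~1 s, i.e. SD 1/6 s, random sign,
#' amplitude `burst_amp_sd * white_sd`) and additional white noise raising
#' their variance by `variance_inflation`. Non-target channels are returned
#' bit-identical.
#'
#' @param rec A [recording()].
#' @param effect An [effect_spec()].
#' @param design 0/1 play indicator aligned with the recording (recycled over
#'   repeated cycles if shorter).
#' @param seed Seed for burst placement and extra noise.
#' @param white_sd White-noise SD defining the burst amplitude unit.
#' @return The modified [recording()].
#' @export
inject_channel_effect <- function(rec, effect, design, seed, white_sd = 0.3) {
  stopifnot(inherits(rec, "recording"), inherits(effect, "effect_spec"))
  n <- nrow(rec$data)
  if (length(design) < n) design <- rep(design, length.out = n)
  design <- design[seq_len(n)]
  unknown <- setdiff(effect$target_channels, rec$channel_ids)
  if (length(unknown) > 0L)
    stop("unknown channel id(s): ", paste(unknown, collapse = ", "))
  if (effect$burst_rate == 0 && effect$variance_inflation == 1)
    return(rec)
  play_idx <- which(design == 1)
  if (length(play_idx) == 0L) return(rec)
  cols <- match(effect$target_channels, rec$channel_ids)
  burst_sd_s <- 1 / 6
  tm <- (seq_len(n) - 1L) / rec$rate_hz
  # per-cycle play blocks: contiguous runs of the indicator
  runs <- split(play_idx, cumsum(c(1, diff(play_idx) != 1)))
  data <- rec$data
  withr::with_seed(as.integer(seed), {
    for (j in cols) {
      for (run in runs) {
        n_bursts <- stats::rpois(1, effect$burst_rate)
        # placements are drawn whenever bursts occur so that configurations
        # differing only in amplitude share the same realisation
        if (n_bursts > 0) {
          centers <- tm[sample(run, n_bursts, replace = TRUE)]
          signs <- sample(c(-1, 1), n_bursts, replace = TRUE)
          for (b in seq_len(n_bursts)) {
            bump <- signs[b] * effect$burst_amp_sd * white_sd *
              exp(-0.5 * ((tm[run] - centers[b]) / burst_sd_s)^2)
            data[run, j] <- data[run, j] + bump
          }
        }
      }
      if (effect$variance_inflation > 1) {
        extra_sd <- white_sd * sqrt(effect$variance_inflation - 1)
        data[play_idx, j] <- data[play_idx, j] +
          stats::rnorm(length(play_idx), 0, extra_sd)
      }
    }
  })
  rec$data <- data
  rec
}

#' Simulate a labelled cohort
#'
#' For each subject, one `score` recording (never injected) and one `improv`
#' recording; improv recordings of the groups named in
#' `config$effect_groups` (default: pianists) receive the planted effect.
#' Fully deterministic given `config$seed`.
#'
#' @param config A [cohort_config()].
#' @return A `cohort_data` object: `recordings` (list of [recording()]) and
#'   `manifest` (subject_id, group, task, file, seed).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  design <- rep(make_block_design(config$timing, config$rate_hz),
                config$repeat_cycles)
  ids <- c(sprintf("P%02d", seq_len(config$n_group_a)),
           sprintf("N%02d", seq_len(config$n_group_b)))
  groups <- rep(c("pianist", "non_pianist"),
                c(config$n_group_a, config$n_group_b))
  recs <- list()
  rows <- list()
  for (i in seq_along(ids)) {
    subject_seed <- derive_seed(config$seed, i)
    for (task in TASK_LEVELS) {
      rec <- simulate_recording(config, groups[i], task, subject_seed,
                                subject_id = ids[i])
      if (task == "improv" && groups[i] %in% config$effect_groups) {
        rec <- inject_channel_effect(rec, config$effect, design,
                                     seed = derive_seed(subject_seed, 3L),
                                     white_sd = config$noise$white_sd)
      }
      recs[[length(recs) + 1L]] <- rec
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = ids[i], group = groups[i], task = task,
        file = NA_character_, seed = subject_seed)
    }
  }
  manifest <- do.call(rbind, rows)
  class(manifest) <- c("cohort_manifest", "data.frame")
  structure(list(recordings = recs, manifest = manifest),
            class = "cohort_data")
}

#' @export
print.cohort_data <- function(x, ...) {
  cat("<cohort_data>", length(x$recordings), "recordings,",
      length(unique(x$manifest$subject_id)), "subjects (",
      sum(x$manifest$group == "pianist" & x$manifest$task == "score"),
      "pianist /",
      sum(x$manifest$group == "non_pianist" & x$manifest$task == "score"),
      "non-pianist )\n")
  invisible(x)
}
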