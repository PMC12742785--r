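# Shared fixtures, all generated in code.

# small cohort for fast pipeline tests
tiny_cohort_config <- function(seed = 1L, ...) {
  cohort_config(n_group_a = 3L, n_group_b = 2L, seed = seed, ...)
}

tiny_pipeline_config <- function(cc, ...) {
  args <- list(synthetic = cc, target_len = 400L, windows = 20L,
               stride = 25L, epochs = 3L, batch_size = 64L,
               n_replicates = 1L, n_perm = 200L, master_seed = cc$seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(pipeline_config, args)
}

random_recording <- function(n = 50L, C = 4L, seed = 1L, task = "score",
                             group = "pianist", subject_id = "S01",
                             rate_hz = 8) {
  withr::with_seed(seed, {
    recording(matrix(stats::rnorm(n * C), n, C), subject_id = subject_id,
              group = group, task = task, rate_hz = rate_hz)
  })
}

# minimal processed-hemoglobin SNIRF fixture written with rhdf5
write_snirf_fixture <- function(path, data, labels, rate_hz = 8) {
  n <- nrow(data)
  rhdf5::h5createFile(path)
  rhdf5::h5createGroup(path, "nirs")
  rhdf5::h5createGroup(path, "nirs/data1")
  rhdf5::h5write(data, path, "nirs/data1/dataTimeSeries")
  rhdf5::h5write((seq_len(n) - 1) / rate_hz, path, "nirs/data1/time")
  for (i in seq_along(labels)) {
    grp <- sprintf("nirs/data1/measurementList%d", i)
    rhdf5::h5createGroup(path, grp)
    rhdf5::h5write(labels[i], path, paste0(grp, "/dataTypeLabel"))
    rhdf5::h5write(1L, path, paste0(grp, "/sourceIndex"))
    rhdf5::h5write(i, path, paste0(grp, "/detectorIndex"))
  }
  rhdf5::h5closeAll()
  invisible(path)
}

# manifest assembled in memory (no files on disk)
memory_manifest <- function(subject_ids, groups) {
  rows <- expand.grid(task = c("score", "improv"), subject_id = subject_ids,
                      stringsAsFactors = FALSE)
  rows$group <- groups[match(rows$subject_id, subject_ids)]
  rows$file <- NA_character_
  m <- rows[, c("subject_id", "group", "task", "file")]
  class(m) <- c("cohort_manifest", "data.frame")
  m
}
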