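#' @importFrom data.table := .N .SD
NULL

GROUP_LEVELS <- c("pianist", "non_pianist")
TASK_LEVELS <- c("score", "improv")

#' Construct a Recording
#'
#' A Recording is one subject's one-task multichannel hemodynamic time
#' series: a `time x channel` matrix of hemoglobin concentration change
#' (arbitrary concentration units) plus metadata.
#'
#' @param data Numeric matrix, time by channel; all values must be finite.
#' @param subject_id Subject identifier string.
#' @param group Group label, `"pianist"` or `"non_pianist"`.
#' @param task Task label, `"score"` or `"improv"`.
#' @param rate_hz Sampling rate in Hz.
#' @param channel_ids Ordered integer channel identifiers (1-based montage
#'   numbering; default `1:ncol(data)`).
#' @return An object of class `recording`.
#' @export
recording <- function(data, subject_id, group, task, rate_hz,
                      channel_ids = seq_len(ncol(data))) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (!all(is.finite(data))) stop("recording data contains non-finite values")
  group <- match.arg(group, GROUP_LEVELS)
  task <- match.arg(task, TASK_LEVELS)
  if (!(is.numeric(rate_hz) && length(rate_hz) == 1L && rate_hz > 0))
    stop("rate_hz must be a positive number")
  channel_ids <- as.integer(channel_ids)
  if (anyDuplicated(channel_ids)) stop("channel_ids must be unique")
  if (length(channel_ids) != ncol(data))
    stop("channel_ids length must equal the number of data columns")
  colnames(data) <- sprintf("ch%02d", channel_ids)
  structure(
    list(subject_id = as.character(subject_id), group = group, task = task,
         rate_hz = as.numeric(rate_hz), channel_ids = channel_ids,
         data = data),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  cat("<recording>", x$subject_id, paste0("(", x$group, ", ", x$task, "):"),
      nrow(x$data), "samples x", ncol(x$data), "channels @", x$rate_hz, "Hz\n")
  invisible(x)
}

#' Read a recording from a wide CSV file
#'
#' Expects a header `time,ch01,...,chNN`, one row per sample. The time column
#' must be uniformly spaced (relative tolerance `1e-6`); the sampling rate is
#' inferred from the spacing when not supplied. Malformed values are errors,
#' never imputed.
#'
#' @param path CSV file path.
#' @param subject_id,group,task Recording metadata (see [recording()]).
#' @param rate_hz Sampling rate; inferred from the time column if `NULL`.
#' @return A [recording()].
#' @export
read_wide_csv <- function(path, subject_id = "unknown", group = "pianist",
                          task = "score", rate_hz = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  fields <- utils::count.fields(path, sep = ",")
  if (length(fields) > 1L && any(fields != fields[1L])) {
    r <- which(fields != fields[1L])[1L] - 1L
    stop("format error in ", path, ": ragged row at data row ", r)
  }
  dt <- data.table::fread(path, header = TRUE, fill = FALSE,
                          colClasses = "numeric", data.table = TRUE)
  nm <- names(dt)
  if (length(nm) < 2L || nm[1L] != "time" || !all(grepl("^ch[0-9]+$", nm[-1L])))
    stop("format error in ", path,
         ": header must be time,ch01,...,chNN (got: ",
         paste(utils::head(nm, 4L), collapse = ","), ", ...)")
  m <- as.matrix(dt)
  bad <- which(!is.finite(m), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    r <- min(bad[, 1L])
    stop("format error in ", path, ": non-finite value at data row ", r,
         " (column ", nm[bad[which.min(bad[, 1L]), 2L]], ")")
  }
  tm <- m[, 1L]
  if (length(tm) >= 3L) {
    dts <- diff(tm)
    step <- dts[1L]   # the first interval sets the expected spacing
    if (step <= 0 || any(abs(dts - step) > 1e-6 * max(abs(step), 1e-12))) {
      r <- which(abs(dts - step) > 1e-6 * max(abs(step), 1e-12))[1L] + 1L
      stop("format error in ", path, ": non-uniform time spacing at data row ", r)
    }
    inferred_rate <- 1 / step
  } else if (length(tm) == 2L) {
    inferred_rate <- 1 / (tm[2L] - tm[1L])
  } else {
    inferred_rate <- NA_real_
  }
  if (is.null(rate_hz)) {
    if (is.na(inferred_rate))
      stop("cannot infer rate_hz from fewer than 2 samples; supply rate_hz")
    rate_hz <- inferred_rate
  }
  ids <- as.integer(sub("^ch", "", nm[-1L]))
  recording(m[, -1L, drop = FALSE], subject_id = subject_id, group = group,
            task = task, rate_hz = rate_hz, channel_ids = ids)
}

#' Write a recording to a wide CSV file
#'
#' The inverse of [read_wide_csv()]: a `time` column starting at 0 with step
#' `1/rate_hz`, then one column per channel, values serialised with 12
#' significant digits so round-trips agree to better than `1e-9`.
#'
#' @param rec A [recording()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_wide_csv <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  n <- nrow(rec$data)
  header <- paste(c("time", sprintf("ch%02d", rec$channel_ids)),
                  collapse = ",")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(header, con)
  if (n > 0L) {
    tm <- (seq_len(n) - 1L) / rec$rate_hz
    body <- cbind(sprintf("%.12g", tm),
                  matrix(sprintf("%.12g", rec$data), n))
    writeLines(do.call(paste, c(asplit(body, 2L), sep = ",")), con)
  }
  invisible(path)
}

#' Read one chromophore from a SNIRF file
#'
#' Reads a processed-hemoglobin continuous-wave SNIRF file (the community
#' HDF5 interchange format for fNIRS) and returns the requested chromophore's
#' time series. Channels are taken in file order and mapped to ids `1..n`;
#' montages larger than 15 channels are rejected. Requires the `rhdf5`
#' package.
#'
#' @param path SNIRF (HDF5) file path.
#' @param chromophore `"HbO"` (default) or `"HbR"`.
#' @param subject_id,group,task Recording metadata.
#' @return A [recording()].
#' @export
read_snirf_hbo <- function(path, chromophore = c("HbO", "HbR"),
                           subject_id = "unknown", group = "pianist",
                           task = "score") {
  chromophore <- match.arg(chromophore)
  if (!requireNamespace("rhdf5", quietly = TRUE))
    stop("reading SNIRF files requires the 'rhdf5' package")
  if (!file.exists(path)) stop("file not found: ", path)
  contents <- rhdf5::h5ls(path)
  nirs_groups <- contents$name[contents$otype == "H5I_GROUP" &
                               contents$group == "/" &
                               grepl("^nirs[0-9]*$", contents$name)]
  if (length(nirs_groups) == 0L)
    stop("unsupported content: no /nirs group in ", path)
  root <- paste0("/", nirs_groups[1L], "/data1")
  series <- rhdf5::h5read(path, paste0(root, "/dataTimeSeries"))
  tvec <- as.numeric(rhdf5::h5read(path, paste0(root, "/time")))
  series <- as.matrix(series)
  # SNIRF stores time x measurement; transposed files are recognisable from
  # the time vector length
  if (nrow(series) != length(tvec) && ncol(series) == length(tvec))
    series <- t(series)
  if (nrow(series) != length(tvec))
    stop("unsupported content: dataTimeSeries shape does not match /time")
  ml_names <- contents$name[grepl("^measurementList[0-9]+$", contents$name) &
                            contents$group == root]
  ml_names <- ml_names[order(as.integer(sub("^measurementList", "", ml_names)))]
  if (length(ml_names) != ncol(series))
    stop("unsupported content: measurementList count does not match columns")
  labels <- vapply(ml_names, function(nm) {
    lab <- try(rhdf5::h5read(path, paste0(root, "/", nm, "/dataTypeLabel")),
               silent = TRUE)
    if (inherits(lab, "try-error")) "" else as.character(lab)[1L]
  }, character(1L))
  keep <- which(labels == chromophore)
  if (length(keep) == 0L)
    stop("unsupported content: no ", chromophore, " measurements in ", path,
         " (found: ", paste(unique(labels), collapse = ", "), ")")
  if (length(keep) > 15L)
    stop("unsupported content: ", length(keep),
         " channels exceed the supported 15-channel montage")
  if (length(tvec) < 2L) stop("unsupported content: fewer than 2 samples")
  rate <- 1 / stats::median(diff(tvec))
  recording(series[, keep, drop = FALSE], subject_id = subject_id,
            group = group, task = task, rate_hz = rate,
            channel_ids = seq_along(keep))
}

#' Load and validate a cohort manifest
#'
#' A manifest CSV lists one row per (subject, task) recording: columns
#' `subject_id`, `group`, `task`, `file`, and optionally `seed`. Group must
#' be one of `pianist`/`non_pianist`, task one of `score`/`improv`;
#' duplicated (subject, task) pairs are an error. Relative file paths are
#' resolved against the manifest's directory.
#'
#' @param path Manifest CSV path.
#' @param check_files Verify that every referenced file exists (default TRUE).
#' @return A data frame of class `cohort_manifest`.
#' @export
load_manifest <- function(path, check_files = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("subject_id", "group", "task", "file")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L)
    stop("manifest is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  bad_group <- setdiff(unique(df$group), GROUP_LEVELS)
  if (length(bad_group) > 0L)
    stop("unknown group value(s): ", paste(bad_group, collapse = ", "),
         "; allowed: ", paste(GROUP_LEVELS, collapse = ", "))
  bad_task <- setdiff(unique(df$task), TASK_LEVELS)
  if (length(bad_task) > 0L)
    stop("unknown task value(s): ", paste(bad_task, collapse = ", "),
         "; allowed: ", paste(TASK_LEVELS, collapse = ", "))
  key <- paste(df$subject_id, df$task)
  if (anyDuplicated(key))
    stop("duplicate (subject_id, task) entry: ", key[duplicated(key)][1L])
  if (check_files) {
    paths <- ifelse(file.exists(df$file), df$file,
                    file.path(dirname(path), df$file))
    missing <- !file.exists(paths)
    if (any(missing))
      stop("manifest references missing file(s): ",
           paste(utils::head(df$file[missing], 3L), collapse = ", "))
    df$file <- paths
  }
  class(df) <- c("cohort_manifest", "data.frame")
  df
}

#' Write a cohort (recordings + manifest) to disk
#'
#' Writes each recording as a wide CSV named `<subject>_<task>.csv` and a
#' manifest CSV (`manifest.csv`) referencing them.
#'
#' @param cohort A `cohort_data` object from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort_data"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(length(cohort$recordings))
  for (i in seq_along(cohort$recordings)) {
    rec <- cohort$recordings[[i]]
    files[i] <- paste0(rec$subject_id, "_", rec$task, ".csv")
    write_wide_csv(rec, file.path(dir, files[i]))
  }
  manifest <- cohort$manifest
  manifest$file <- files
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load all recordings referenced by a manifest
#'
#' @param manifest A `cohort_manifest` from [load_manifest()].
#' @param rate_hz Optional sampling rate override (otherwise inferred from
#'   each file's time column).
#' @return A `cohort_data` object: list of [recording()]s plus the manifest.
#' @export
load_cohort <- function(manifest, rate_hz = NULL) {
  stopifnot(inherits(manifest, "cohort_manifest"))
  recs <- lapply(seq_len(nrow(manifest)), function(i) {
    read_wide_csv(manifest$file[i], subject_id = manifest$subject_id[i],
                  group = manifest$group[i], task = manifest$task[i],
                  rate_hz = rate_hz)
  })
  structure(list(recordings = recs, manifest = manifest),
            class = "cohort_data")
}
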