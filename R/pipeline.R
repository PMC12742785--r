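#' End-to-end pipeline configuration
#'
#' Points the pipeline at a data source (a cohort manifest on disk, or a
#' synthetic [cohort_config()]), and collects the preprocessing, training,
#' replication, and inference knobs.
#'
#' @param synthetic A [cohort_config()], or `NULL` when loading from disk.
#' @param manifest Path to a manifest CSV, or `NULL` when simulating.
#' @param target_len Uniform recording length after resampling (default 1800
#'   samples).
#' @param windows Window-size candidates for the sweep (default 15, 20, 25).
#' @param stride Sliding-window stride (default 1).
#' @param epochs,batch_size,learning_rate,validation_fraction Training knobs,
#'   see [train_config()].
#' @param n_replicates Training replicates per window size (default 5); each
#'   replicate r uses seed `master_seed + r`.
#' @param roi_channels A-priori ROI for group inference (default 1 and 15).
#' @param n_perm Label permutations for the permutation test (default 10000).
#' @param master_seed Master seed; all replicate and inference seeds derive
#'   from it.
#' @param outdir Output directory for reports and figures, or `NULL`.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(synthetic = NULL, manifest = NULL,
                            target_len = 1800L, windows = c(15L, 20L, 25L),
                            stride = 1L, epochs = 200L, batch_size = 1024L,
                            learning_rate = 1e-3, validation_fraction = 0.2,
                            n_replicates = 5L, roi_channels = c(1L, 15L),
                            n_perm = 10000L, master_seed = 1L, outdir = NULL) {
  if (is.null(synthetic) && is.null(manifest))
    stop("provide either a synthetic cohort_config or a manifest path")
  if (!is.null(synthetic)) stopifnot(inherits(synthetic, "cohort_config"))
  if (length(windows) == 0L) stop("windows must be non-empty")
  if (n_replicates < 1L) stop("n_replicates must be >= 1")
  structure(list(
    synthetic = synthetic, manifest = manifest,
    target_len = as.integer(target_len),
    windows = sort(unique(as.integer(windows))),
    stride = as.integer(stride),
    epochs = as.integer(epochs), batch_size = as.integer(batch_size),
    learning_rate = learning_rate,
    validation_fraction = validation_fraction,
    n_replicates = as.integer(n_replicates),
    roi_channels = as.integer(roi_channels),
    n_perm = as.integer(n_perm),
    master_seed = as.integer(master_seed),
    outdir = outdir
  ), class = "pipeline_config")
}

# compact, JSON-stable echo of the configuration for provenance checks
config_fingerprint <- function(config) {
  cfg <- unclass(config)
  cfg$outdir <- NULL
  if (!is.null(cfg$synthetic)) {
    cfg$synthetic <- lapply(unclass(cfg$synthetic), function(x)
      if (inherits(x, c("task_timing", "noise_params", "effect_spec")))
        unclass(x) else x)
  }
  as.character(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                                null = "null"))
}

#' Run the full replicated analysis
#'
#' Resamples every recording to the uniform length, fits the per-channel
#' normaliser on the reference (score) task only, and then, for every window
#' size candidate and replicate: cuts sliding windows, trains the LSTM
#' autoencoder on score windows (seed = `master_seed` + replicate index), and
#' scores both tasks by per-channel reconstruction error. Replicate-averaged
#' errors drive window-size selection; the group comparison runs only at the
#' selected window size.
#'
#' @param config A [pipeline_config()].
#' @param cohort Optionally, an in-memory `cohort_data` (overrides the
#'   config's data source).
#' @return An `analysis_report` (also written to `config$outdir` when set).
#' @export
run_pipeline <- function(config, cohort = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(cohort)) {
    cohort <- if (!is.null(config$synthetic)) {
      simulate_cohort(config$synthetic)
    } else {
      load_cohort(load_manifest(config$manifest))
    }
  }
  recs <- lapply(cohort$recordings, resample_to_length,
                 target_len = config$target_len)
  tasks <- vapply(recs, `[[`, "", "task")
  score_recs <- recs[tasks == "score"]
  improv_recs <- recs[tasks == "improv"]
  if (length(score_recs) == 0L) stop("stage preprocess: no score recordings")
  if (length(improv_recs) == 0L) stop("stage preprocess: no improv recordings")
  norm <- fit_normalizer(score_recs)
  score_recs <- lapply(score_recs, apply_normalizer, stats = norm)
  improv_recs <- lapply(improv_recs, apply_normalizer, stats = norm)
  channel_ids <- score_recs[[1L]]$channel_ids

  sweep_rows <- list()
  sel <- NULL   # per-replicate results retained for every W (small matrices)
  results <- list()
  for (W in config$windows) {
    win_score <- sliding_windows(score_recs, W, config$stride)
    win_improv <- sliding_windows(improv_recs, W, config$stride)
    reps <- list()
    for (r in seq_len(config$n_replicates)) {
      seed_r <- config$master_seed + r
      spec <- model_spec(W, length(channel_ids))
      handle <- build_autoencoder(spec, seed = seed_r)
      cfg_t <- train_config(epochs = config$epochs,
                            batch_size = config$batch_size,
                            learning_rate = config$learning_rate,
                            validation_fraction = config$validation_fraction,
                            seed = seed_r)
      history <- train_autoencoder(handle, win_score, cfg_t)
      err_score <- reconstruction_errors(handle, win_score)
      err_improv <- reconstruction_errors(handle, win_improv)
      val_idx <- handle$env$val_idx
      train_idx <- setdiff(seq_len(nrow(err_score)), val_idx)
      reps[[r]] <- list(
        seed = seed_r,
        history = history,
        err_score = err_score,
        err_improv = err_improv,
        val_idx = val_idx,
        train_error = mean(err_score[train_idx, ]),
        test_error = mean(err_improv)
      )
    }
    sweep_rows[[length(sweep_rows) + 1L]] <- data.frame(
      window_size = W,
      train_error = mean(vapply(reps, `[[`, 0, "train_error")),
      test_error = mean(vapply(reps, `[[`, 0, "test_error"))
    )
    results[[as.character(W)]] <- list(reps = reps, win_score = win_score,
                                       win_improv = win_improv)
  }
  sweep_table <- do.call(rbind, sweep_rows)
  selected <- select_window_size(sweep_table)
  res <- results[[as.character(selected)]]
  reps <- res$reps

  avg_err_improv <- Reduce(`+`, lapply(reps, `[[`, "err_improv")) / length(reps)
  avg_err_score <- Reduce(`+`, lapply(reps, `[[`, "err_score")) / length(reps)
  all_err <- rbind(avg_err_score, avg_err_improv)
  all_prov <- rbind(res$win_score$provenance, res$win_improv$provenance)
  errmap <- subject_channel_error(all_err, all_prov, channel_ids)
  ranking <- rank_channels(errmap, task = "improv")

  roi_cols <- match(config$roi_channels, channel_ids)
  if (anyNA(roi_cols)) stop("stage stats: ROI channels not in montage")
  heldout_roi <- vapply(reps, function(rp)
    mean(rp$err_score[rp$val_idx, roi_cols, drop = FALSE]), 0)
  improv_roi <- vapply(reps, function(rp)
    mean(rp$err_improv[, roi_cols, drop = FALSE]), 0)

  comparison <- compare_groups(avg_err_improv, res$win_improv$provenance,
                               cohort$manifest,
                               roi_channels = config$roi_channels,
                               channel_ids = channel_ids,
                               n_perm = config$n_perm,
                               seed = config$master_seed)

  histories <- lapply(reps, `[[`, "history")
  report <- structure(list(
    sweep_table = sweep_table,
    selected_window = selected,
    channel_ranking = ranking,
    error_map = errmap,
    comparison = comparison,
    histories = histories,
    heldout_score_roi_error = mean(heldout_roi),
    improv_roi_error = mean(improv_roi),
    heldout_score_roi_error_by_replicate = heldout_roi,
    improv_roi_error_by_replicate = improv_roi,
    replicate_seeds = vapply(reps, `[[`, 0, "seed"),
    master_seed = config$master_seed,
    config_fingerprint = config_fingerprint(config)
  ), class = "analysis_report")
  if (!is.null(config$outdir)) render_report(report, config$outdir)
  report
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("<analysis_report> selected window:", x$selected_window, "\n")
  print(x$sweep_table, row.names = FALSE)
  cat("top channels (improv):",
      paste(utils::head(x$channel_ranking$channel, 3L), collapse = ", "), "\n")
  cat(sprintf("ROI error: improv %.4g vs held-out score %.4g\n",
              x$improv_roi_error, x$heldout_score_roi_error))
  print(x$comparison)
  invisible(x)
}

report_to_list <- function(report) {
  list(
    selected_window = report$selected_window,
    sweep_table = report$sweep_table,
    channel_ranking = report$channel_ranking,
    error_map_subject = report$error_map$subject,
    error_map_grand = report$error_map$grand,
    comparison = list(
      summaries = report$comparison$summaries,
      tests = report$comparison$tests,
      effect_sizes = lapply(report$comparison$effect_sizes, unclass),
      roi_channels = report$comparison$roi_channels,
      n_a = report$comparison$n_a, n_b = report$comparison$n_b
    ),
    final_losses = data.frame(
      replicate = seq_along(report$histories),
      train_loss = vapply(report$histories, function(h) utils::tail(h$train_loss, 1L), 0),
      val_loss = vapply(report$histories, function(h) utils::tail(h$val_loss, 1L), 0)
    ),
    heldout_score_roi_error = report$heldout_score_roi_error,
    improv_roi_error = report$improv_roi_error,
    replicate_seeds = report$replicate_seeds,
    master_seed = report$master_seed,
    config_fingerprint = report$config_fingerprint
  )
}

#' Write an analysis report as JSON
#'
#' Deterministic serialisation: no timestamps, full precision; identical
#' pipeline runs produce byte-identical files.
#'
#' @param report An `analysis_report`.
#' @param path Output JSON path.
#' @return The path, invisibly.
#' @export
save_report_json <- function(report, path) {
  stopifnot(inherits(report, "analysis_report"))
  jsonlite::write_json(report_to_list(report), path, auto_unbox = TRUE,
                       digits = NA, dataframe = "columns", null = "null")
  invisible(path)
}

#' Load a report JSON, verifying its configuration fingerprint
#'
#' @param path Report JSON path.
#' @param config The [pipeline_config()] the report is expected to match, or
#'   `NULL` to skip the check.
#' @param force Load even when the fingerprint mismatches.
#' @return The parsed report list.
#' @export
load_report_json <- function(path, config = NULL, force = FALSE) {
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(config) && !force) {
    fp <- config_fingerprint(config)
    if (!identical(fp, rep$config_fingerprint))
      stop("report at ", path, " was produced by a different configuration; ",
           "pass force = TRUE to load anyway")
  }
  rep
}

#' Render report files: figures, JSON, and a text summary
#'
#' Writes a training/validation loss-curve figure, a channel-wise error bar
#' figure (per-group panels plus the overall average, mean +/- SD across
#' subjects), the deterministic JSON report, and a human-readable summary.
#'
#' @param report An `analysis_report`.
#' @param outdir Output directory (created if needed).
#' @return Character vector of written file paths, invisibly.
#' @export
render_report <- function(report, outdir) {
  stopifnot(inherits(report, "analysis_report"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)

  # loss curves over replicates
  hist_df <- do.call(rbind, lapply(seq_along(report$histories), function(i) {
    h <- report$histories[[i]]
    data.frame(replicate = factor(i), epoch = rep(h$epoch, 2L),
               loss = c(h$train_loss, h$val_loss),
               which = rep(c("training", "validation"), each = nrow(h)))
  }))
  p1 <- ggplot2::ggplot(hist_df,
          ggplot2::aes(x = .data$epoch, y = .data$loss,
                       colour = .data$which, linetype = .data$replicate)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "mean squared error", colour = NULL,
                  linetype = "replicate",
                  title = paste0("Training and validation loss (W = ",
                                 report$selected_window, ")")) +
    ggplot2::theme_minimal()
  f1 <- file.path(outdir, "loss_curves.png")
  ggplot2::ggsave(f1, p1, width = 7, height = 4, dpi = 120)
  files <- c(files, f1)

  # channel-wise error bars, improv task: per-group panels + overall
  subj <- report$error_map$subject
  subj <- subj[subj$task == "improv", , drop = FALSE]
  groups <- report$comparison$summaries[, c("subject_id", "group")]
  subj <- merge(subj, groups, by = "subject_id", all.x = TRUE)
  have_groups <- unique(stats::na.omit(subj$group))
  if (length(have_groups) < 2L)
    warning("only one group present; channel figure degrades to fewer panels")
  subj$panel <- ifelse(is.na(subj$group), "ungrouped", subj$group)
  overall <- subj
  overall$panel <- "overall"
  plot_df <- rbind(subj, overall)
  agg <- stats::aggregate(mean_error ~ panel + channel, plot_df, mean)
  agg$sd <- stats::aggregate(mean_error ~ panel + channel, plot_df,
                             stats::sd)$mean_error
  agg$sd[is.na(agg$sd)] <- 0
  p2 <- ggplot2::ggplot(agg,
          ggplot2::aes(x = factor(.data$channel), y = .data$mean_error)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_error - .data$sd,
                                        ymax = .data$mean_error + .data$sd),
                           width = 0.3) +
    ggplot2::facet_wrap(~panel, ncol = 1L) +
    ggplot2::labs(x = "channel", y = "mean reconstruction error",
                  title = "Channel-wise reconstruction errors (improv)") +
    ggplot2::theme_minimal()
  f2 <- file.path(outdir, "channel_errors.png")
  ggplot2::ggsave(f2, p2, width = 7, height = 2.6 * length(unique(agg$panel)),
                  dpi = 120)
  files <- c(files, f2)

  f3 <- file.path(outdir, "report.json")
  save_report_json(report, f3)
  files <- c(files, f3)

  f4 <- file.path(outdir, "summary.txt")
  con <- file(f4, "wb")
  sink(con)
  print(report)
  sink()
  close(con)
  files <- c(files, f4)
  invisible(files)
}

#' Persist an error map as tidy CSV
#'
#' Columns: subject_id, group, task, channel, mean_error.
#'
#' @param errmap A `channel_error_map`.
#' @param manifest Manifest supplying group labels.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_error_map_csv <- function(errmap, manifest, path) {
  stopifnot(inherits(errmap, "channel_error_map"))
  subj <- errmap$subject
  sg <- unique(manifest[, c("subject_id", "group")])
  subj$group <- sg$group[match(subj$subject_id, sg$subject_id)]
  subj <- subj[, c("subject_id", "group", "task", "channel", "mean_error")]
  utils::write.csv(subj, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Group comparison from a tidy error-map CSV
#'
#' Runs the robust-summary group battery on per-channel mean errors stored by
#' [write_error_map_csv()]. Because per-window errors are no longer
#' available, each subject contributes its ROI-averaged per-channel mean
#' error as a single value, and only subject-level tests are run.
#'
#' @param path Tidy error-map CSV.
#' @param roi_channels ROI channel ids.
#' @param n_perm,seed Permutation test parameters.
#' @param task Task to analyse.
#' @return A list with per-subject ROI means by group, the three test
#'   results, and effect sizes.
#' @export
stats_from_error_map <- function(path, roi_channels = c(1L, 15L),
                                 n_perm = 10000L, seed = 1L,
                                 task = "improv") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df <- df[df$task == task & df$channel %in% roi_channels, , drop = FALSE]
  if (nrow(df) == 0L) stop("no ROI rows for task ", task)
  roi <- stats::aggregate(mean_error ~ subject_id + group, df, mean)
  a <- log(pmax(roi$mean_error[roi$group == "pianist"], 1e-12))
  b <- log(pmax(roi$mean_error[roi$group == "non_pianist"], 1e-12))
  list(
    roi_means = roi,
    welch = welch_t_test(a, b),
    mann_whitney = mann_whitney_test(a, b),
    permutation = permutation_test(a, b, n_iter = n_perm, seed = seed),
    effect_sizes = effect_sizes(a, b)
  )
}
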