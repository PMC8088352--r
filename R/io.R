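# File formats: per-subject signal CSVs plus a manifest, feature tables,
# and JSON pipeline configurations. Signals are stored as plain CSV
# (columns = channels, rows = samples) - the text-format alternative to EDF;
# no EDF library is assumed by the package.

#' Write a cohort to disk
#'
#' One CSV per subject (columns named by channel, one row per sample) under
#' `dir/signals/`, plus `dir/manifest.csv` with columns `subject_id,
#' class_label, path, fs, n_channels`. Full-scale records are large (a 300 s,
#' 19-channel record is ~25 MB of text); intended for cohorts that actually
#' need to be materialized.
#'
#' @param cohort List of [eeg_record()] objects.
#' @param dir Output directory (created if missing).
#' @return The manifest as a data.frame, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(is.list(cohort), length(cohort) > 0)
  sig_dir <- file.path(dir, "signals")
  dir.create(sig_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort, function(rec) {
    stopifnot(inherits(rec, "eeg_record"))
    rel <- file.path("signals", paste0(rec$subject_id, ".csv"))
    dt <- data.table::as.data.table(t(rec$samples))
    data.table::setnames(dt, rec$channel_labels)
    data.table::fwrite(dt, file.path(dir, rel))
    data.frame(subject_id = rec$subject_id, class_label = rec$class_label,
               path = rel, fs = rec$fs, n_channels = nrow(rec$samples))
  })
  manifest <- do.call(rbind, rows)
  data.table::fwrite(manifest, file.path(dir, "manifest.csv"))
  invisible(manifest)
}

#' Read a cohort back from a manifest
#'
#' @param manifest_path Path to a `manifest.csv` written by [write_cohort()]
#'   (signal paths are resolved relative to its directory).
#' @return List of [eeg_record()] objects.
#' @export
read_signals <- function(manifest_path) {
  if (!file.exists(manifest_path)) stop("manifest not found: ", manifest_path)
  base <- dirname(manifest_path)
  manifest <- data.table::fread(manifest_path, data.table = FALSE)
  need <- c("subject_id", "class_label", "path", "fs", "n_channels")
  if (!all(need %in% names(manifest)))
    stop("manifest is missing columns: ",
         paste(setdiff(need, names(manifest)), collapse = ", "))
  if (!all(manifest$class_label %in% 1:3))
    stop("manifest class labels must be in {1, 2, 3}")
  lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    fp <- file.path(base, row$path)
    if (!file.exists(fp)) stop("signal file not found: ", fp)
    dt <- data.table::fread(fp, data.table = FALSE)
    bad <- which(!vapply(dt, is.numeric, logical(1)))
    if (length(bad))
      stop(sprintf("non-numeric values in %s, column '%s'",
                   fp, names(dt)[bad[1]]))
    if (ncol(dt) != row$n_channels)
      stop(sprintf("%s: expected %d channels, found %d",
                   fp, row$n_channels, ncol(dt)))
    eeg_record(t(as.matrix(dt)), fs = row$fs, channel_labels = names(dt),
               subject_id = row$subject_id, class_label = row$class_label)
  })
}

#' Write / read a feature table as CSV
#'
#' Columns: `subject_id, label, f1..f7`, labels 1/2/3 (MCI/AD/HC).
#'
#' @param ft A [feature_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_features <- function(ft, path) {
  stopifnot(inherits(ft, "feature_table"))
  data.table::fwrite(as.data.frame(ft), path)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- data.table::fread(path, data.table = FALSE)
  need <- c("subject_id", "label", paste0("f", 1:7))
  if (!all(need %in% names(df)))
    stop("feature CSV is missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  feature_table(t(as.matrix(df[, paste0("f", 1:7)])), df$label, df$subject_id)
}

#' Pipeline configuration
#'
#' A single serializable object holding every tunable of the end-to-end run;
#' round-trips losslessly through JSON via [write_config()] /
#' [read_config()].
#'
#' @param n_per_class,n_channels,duration,fs Cohort geometry, see
#'   [cohort_spec()].
#' @param seed Single global seed; all stage seeds derive from it.
#' @param window_start,window_end,target_fs Analysis window, see
#'   [window_spec()].
#' @param lambda,epsilon,aggregation Feature extraction settings.
#' @param classifiers Character vector among `knn, svm, lda, cnn`.
#' @param train_fraction Train split fraction.
#' @param cnn_epochs,cnn_learning_rate,cnn_batch_size CNN optimizer
#'   settings.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(n_per_class = 64, n_channels = 19,
                            duration = 300, fs = 256, seed = 1,
                            window_start = 60, window_end = 240,
                            target_fs = 256, lambda = 0.1, epsilon = 1e-12,
                            aggregation = "mean",
                            classifiers = c("knn", "svm", "lda", "cnn"),
                            train_fraction = 0.8, cnn_epochs = 200,
                            cnn_learning_rate = 1e-3, cnn_batch_size = 32) {
  stopifnot(all(classifiers %in% c("knn", "svm", "lda", "cnn")))
  # scalars stored as doubles so a JSON round-trip is type-stable
  num <- as.numeric
  cfg <- list(n_per_class = num(n_per_class), n_channels = num(n_channels),
              duration = num(duration), fs = num(fs), seed = num(seed),
              window_start = num(window_start), window_end = num(window_end),
              target_fs = num(target_fs), lambda = num(lambda),
              epsilon = num(epsilon), aggregation = aggregation,
              classifiers = classifiers,
              train_fraction = num(train_fraction),
              cnn_epochs = num(cnn_epochs),
              cnn_learning_rate = num(cnn_learning_rate),
              cnn_batch_size = num(cnn_batch_size))
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path JSON file path.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, raw)
}
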