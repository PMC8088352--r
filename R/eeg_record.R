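# The multichannel EEG record container used throughout the pipeline.

#' Standard 10-20 electrode labels (19 channels)
#'
#' @return Character vector of the 19 scalp electrode names of the
#'   international 10-20 montage, in the conventional anterior-to-posterior
#'   order.
#' @export
#' @examples
#' montage_1020()
montage_1020 <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "T3", "C3", "Cz",
    "C4", "T4", "T5", "P3", "Pz", "P4", "T6", "O1", "O2")
}

#' Construct a multichannel EEG record
#'
#' @param samples Numeric matrix, channels x samples, microvolt scale.
#' @param fs Sampling rate in samples per second.
#' @param channel_labels Optional channel names; defaults to the first
#'   `nrow(samples)` labels of the 10-20 montage.
#' @param subject_id Subject identifier.
#' @param class_label Diagnostic class: 1 = MCI, 2 = AD, 3 = HC, or `NA` when
#'   unknown.
#' @return An object of class `eeg_record`.
#' @export
#' @examples
#' rec <- eeg_record(matrix(rnorm(512), 2, 256), fs = 256)
#' rec
eeg_record <- function(samples, fs, channel_labels = NULL,
                       subject_id = NA_character_, class_label = NA_integer_) {
  if (!is.matrix(samples) || !is.numeric(samples))
    stop("samples must be a numeric matrix (channels x samples)")
  assert_finite(samples, "samples")
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0)
    stop("fs must be a single positive number")
  if (is.null(channel_labels)) {
    if (nrow(samples) <= 19) channel_labels <- montage_1020()[seq_len(nrow(samples))]
    else channel_labels <- paste0("ch", seq_len(nrow(samples)))
  }
  if (length(channel_labels) != nrow(samples))
    stop("channel_labels length must equal the number of channels")
  if (!is.na(class_label) && !class_label %in% 1:3)
    stop("class_label must be 1 (MCI), 2 (AD), 3 (HC) or NA")
  rownames(samples) <- channel_labels
  structure(list(samples = samples, fs = fs,
                 channel_labels = channel_labels,
                 subject_id = subject_id,
                 class_label = as.integer(class_label)),
            class = "eeg_record")
}

#' @export
print.eeg_record <- function(x, ...) {
  cls <- if (is.na(x$class_label)) "unknown"
         else c("MCI", "AD", "HC")[x$class_label]
  cat(sprintf("<eeg_record> %s: %d channels x %d samples @ %g Hz (%.1f s), class %s\n",
              x$subject_id, nrow(x$samples), ncol(x$samples), x$fs,
              ncol(x$samples) / x$fs, cls))
  invisible(x)
}

n_samples <- function(record) ncol(record$samples)
record_duration <- function(record) ncol(record$samples) / record$fs
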