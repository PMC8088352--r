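# Record conditioning: integer-factor decimation to the study rate and
# fixed-window cropping.

#' Analysis window specification
#'
#' The study retains seconds 60-240 of each 300 s record (180 s) after
#' conversion to 256 samples/s. Windowing is half-open `[start, end)` in
#' 0-based samples, so 180 s x 256 Hz = 46080 samples exactly.
#'
#' @param start,end Window bounds in seconds.
#' @param target_fs Target sampling rate in samples/s.
#' @return An object of class `window_spec`.
#' @export
#' @examples
#' window_spec()
window_spec <- function(start = 60, end = 240, target_fs = 256) {
  stopifnot(start >= 0, end > start, target_fs > 0)
  structure(list(start = start, end = end, target_fs = target_fs),
            class = "window_spec")
}

#' Decimate a record to a lower sampling rate
#'
#' Integer-factor decimation only: each channel is low-pass filtered with a
#' zero-phase 8th-order Chebyshev type-I filter (0.05 dB ripple, cutoff at
#' 0.8x the target Nyquist - the common decimation default) and then every
#' r-th sample is kept, where `r = record$fs / target_fs`.
#'
#' @param record An [eeg_record()].
#' @param target_fs Target rate; must divide `record$fs` exactly.
#' @return The decimated [eeg_record()]; returned unchanged when
#'   `record$fs == target_fs`.
#' @export
#' @examples
#' rec <- eeg_record(matrix(rnorm(2 * 1024), 2), fs = 1024)
#' resample_record(rec, 256)
resample_record <- function(record, target_fs) {
  stopifnot(inherits(record, "eeg_record"), target_fs > 0)
  if (target_fs > record$fs)
    stop("upsampling not supported (target_fs > record fs)")
  r <- record$fs / target_fs
  if (abs(r - round(r)) > 1e-9)
    stop("unsupported ratio: record fs must be an integer multiple of target_fs")
  r <- round(r)
  if (r == 1) return(record)
  coefs <- cheby1_lowpass(8, 0.05, 0.8 / r)
  n_out <- floor(n_samples(record) / r)
  idx <- seq(1, by = r, length.out = n_out)
  y <- t(apply(record$samples, 1, function(ch)
    filtfilt_iir(coefs$b, coefs$a, ch)[idx]))
  eeg_record(y, target_fs, record$channel_labels, record$subject_id,
             record$class_label)
}

#' Crop a record to the analysis window
#'
#' Keeps samples in `[start * fs, end * fs)` (half-open, 0-based), so the
#' output has exactly `(end - start) * fs` samples.
#'
#' @param record An [eeg_record()].
#' @param window A [window_spec()]; only `start` and `end` are used.
#' @return The cropped [eeg_record()].
#' @export
#' @examples
#' rec <- eeg_record(matrix(rnorm(3 * 256), 1), fs = 256)
#' extract_window(rec, window_spec(start = 1, end = 2))
extract_window <- function(record, window) {
  stopifnot(inherits(record, "eeg_record"), inherits(window, "window_spec"))
  fs <- record$fs
  lo <- round(window$start * fs)
  hi <- round(window$end * fs)
  if (hi > n_samples(record))
    stop(sprintf("window out of range: record holds %.3f s, window ends at %g s",
                 record_duration(record), window$end))
  out <- record$samples[, (lo + 1):hi, drop = FALSE]
  eeg_record(out, fs, record$channel_labels, record$subject_id,
             record$class_label)
}

#' Full record conditioning
#'
#' Resamples to `window$target_fs` (when needed) and crops to the analysis
#' window - the study's "convert to 256 samples per second, keep 60-240 s"
#' step.
#'
#' @param record An [eeg_record()].
#' @param window A [window_spec()].
#' @return The conditioned [eeg_record()].
#' @export
preprocess_record <- function(record, window = window_spec()) {
  extract_window(resample_record(record, window$target_fs), window)
}
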