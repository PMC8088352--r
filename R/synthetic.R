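# Synthetic three-class EEG cohort generator.
#
# Records are drawn directly in the frequency domain: a complex Gaussian
# spectrum is shaped by an amplitude envelope mixing flat within-band power
# (per the class band weights) with a 1/f "pink" background, then inverse
# transformed. This gives exact control of the expected band-power fractions
# without needing a filter-design library, and every record is a stationary
# Gaussian process - which is what the moment-based features assume.

#' EEG frequency band edges
#'
#' Delta 0.1-4, theta 4-8, alpha 8-12, beta 12-30 and gamma 30-45 Hz. The
#' gamma band is given an explicit 45 Hz upper edge (scalp EEG carries little
#' power beyond, and it keeps all bands below the Nyquist frequency of the
#' 256 Hz study rate with margin).
#'
#' @return A 5 x 2 matrix of band edges in Hz with rownames
#'   `delta, theta, alpha, beta, gamma`.
#' @export
eeg_bands <- function() {
  m <- matrix(c(0.1, 4, 4, 8, 8, 12, 12, 30, 30, 45),
              ncol = 2, byrow = TRUE,
              dimnames = list(c("delta", "theta", "alpha", "beta", "gamma"),
                              c("lo", "hi")))
  m
}

#' Class spectral profile
#'
#' Describes the expected power spectrum of one diagnostic class: relative
#' band powers (summing to 1), the fraction of total power carried by the
#' 1/f background, and a relative amplitude factor applied to the 50 uV RMS
#' reference scale. AD profiles carry more slow-wave (delta + theta) weight
#' and a higher absolute amplitude than HC - the classic "EEG slowing"
#' signature - with MCI intermediate.
#'
#' @param class_label 1 = MCI, 2 = AD, 3 = HC.
#' @param band_weights Named numeric vector of length 5
#'   (`delta, theta, alpha, beta, gamma`), nonnegative, summing to 1.
#' @param pink_noise_fraction Fraction of total power given to the 1/f
#'   background, in `[0, 1]`.
#' @param amplitude Relative RMS amplitude factor (1 = 50 uV).
#' @return An object of class `spectral_profile`.
#' @export
#' @examples
#' spectral_profile(3, c(delta = .15, theta = .15, alpha = .45,
#'                       beta = .2, gamma = .05))
spectral_profile <- function(class_label, band_weights,
                             pink_noise_fraction = 0.15, amplitude = 1) {
  stopifnot(class_label %in% 1:3)
  if (length(band_weights) != 5 || any(band_weights < 0))
    stop("band_weights must be 5 nonnegative values")
  if (abs(sum(band_weights) - 1) > 1e-9)
    stop("band_weights must sum to 1 (within 1e-9)")
  if (pink_noise_fraction < 0 || pink_noise_fraction > 1)
    stop("pink_noise_fraction must be in [0, 1]")
  stopifnot(amplitude > 0)
  names(band_weights) <- rownames(eeg_bands())
  structure(list(class_label = as.integer(class_label),
                 band_weights = band_weights,
                 pink_noise_fraction = pink_noise_fraction,
                 amplitude = amplitude),
            class = "spectral_profile")
}

#' Default class profiles
#'
#' Calibrated for a well-separated but not trivial three-class problem:
#' AD slow-wave (delta + theta) weight > MCI > HC, HC alpha weight > AD
#' alpha weight, and amplitude factors HC 1.00 < MCI 1.15 < AD 1.30
#' reflecting the increased absolute slow-wave power that accompanies EEG
#' slowing.
#'
#' @return Named list of three [spectral_profile()] objects
#'   (`MCI`, `AD`, `HC`).
#' @export
default_profiles <- function() {
  list(
    MCI = spectral_profile(1, c(delta = 0.22, theta = 0.20, alpha = 0.33,
                                beta = 0.20, gamma = 0.05), amplitude = 1.15),
    AD  = spectral_profile(2, c(delta = 0.40, theta = 0.30, alpha = 0.15,
                                beta = 0.12, gamma = 0.03), amplitude = 1.30),
    HC  = spectral_profile(3, c(delta = 0.10, theta = 0.10, alpha = 0.45,
                                beta = 0.28, gamma = 0.07), amplitude = 1.00)
  )
}

#' Cohort specification
#'
#' @param n_per_class Subjects per class (study geometry: 64).
#' @param n_channels Number of channels (19, the 10-20 montage).
#' @param duration Record length in seconds (300).
#' @param fs Sampling rate in samples/s (256).
#' @param seed Integer master seed for the cohort.
#' @param profiles List of three [spectral_profile()] objects, one per class.
#' @return An object of class `cohort_spec`.
#' @export
#' @examples
#' cohort_spec(n_per_class = 2, duration = 10, seed = 7)
cohort_spec <- function(n_per_class = 64, n_channels = 19, duration = 300,
                        fs = 256, seed = 1, profiles = default_profiles()) {
  stopifnot(n_per_class >= 1, n_channels >= 1, fs > 0, duration > 0)
  if (abs(duration * fs - round(duration * fs)) > 1e-9)
    stop("duration * fs must be an integer sample count")
  if (length(profiles) != 3) stop("profiles must have one entry per class")
  labs <- vapply(profiles, function(p) p$class_label, integer(1))
  if (!setequal(labs, 1:3)) stop("profiles must cover class labels 1, 2, 3")
  structure(list(n_per_class = as.integer(n_per_class),
                 n_channels = as.integer(n_channels),
                 duration = duration, fs = fs, seed = as.integer(seed),
                 profiles = profiles[order(labs)]),
            class = "cohort_spec")
}

# squared-amplitude spectral envelope on the FFT frequency grid (symmetric,
# zero at DC and outside [0.1, 45] Hz), normalized so sum(A2) = 1
spectral_envelope <- function(profile, n, fs) {
  bands <- eeg_bands()
  if (max(bands) >= fs / 2)
    stop("band edge at or above the Nyquist frequency; increase fs")
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)            # fold to [0, fs/2]
  a2 <- numeric(n)
  for (b in seq_len(nrow(bands))) {
    sel <- f >= bands[b, "lo"] & f < bands[b, "hi"]
    if (any(sel))
      a2[sel] <- a2[sel] + (1 - profile$pink_noise_fraction) *
        profile$band_weights[b] / sum(sel)
  }
  inb <- f >= bands[1, "lo"] & f < bands[5, "hi"]
  pink <- numeric(n)
  pink[inb] <- 1 / f[inb]
  if (sum(pink) > 0) pink <- pink / sum(pink)
  a2 + profile$pink_noise_fraction * pink
}

# one zero-mean unit-variance-ish channel with the envelope's spectrum
draw_shaped_channel <- function(amp_env, n) {
  w <- complex(real = rnorm(n), imaginary = rnorm(n))
  Re(fft(amp_env * w, inverse = TRUE)) / sqrt(n)
}

#' Generate one synthetic EEG record
#'
#' Channels are independent Gaussian draws sharing the class spectral
#' envelope, mixed with a common-source channel (mixing coefficient 0.3,
#' variance preserving) to mimic the shared cortical drive of a monopolar
#' montage. The whole record is scaled to `50 * profile$amplitude` uV RMS.
#' Deterministic given `subject_seed`.
#'
#' @param profile A [spectral_profile()].
#' @param spec A [cohort_spec()] (supplies geometry: channels, duration, fs).
#' @param subject_seed Integer seed for this record.
#' @return An [eeg_record()].
#' @export
#' @examples
#' rec <- generate_record(default_profiles()$HC,
#'                        cohort_spec(n_per_class = 1, duration = 4), 42)
generate_record <- function(profile, spec, subject_seed) {
  stopifnot(inherits(profile, "spectral_profile"), inherits(spec, "cohort_spec"))
  n <- round(spec$duration * spec$fs)
  if (n < 8) stop("record too short")
  amp_env <- sqrt(spectral_envelope(profile, n, spec$fs))
  alpha <- 0.3
  set.seed(subject_seed)
  common <- draw_shaped_channel(amp_env, n)
  x <- matrix(0, spec$n_channels, n)
  for (ch in seq_len(spec$n_channels))
    x[ch, ] <- sqrt(1 - alpha^2) * draw_shaped_channel(amp_env, n) +
      alpha * common
  target_rms <- 50 * profile$amplitude
  x <- x * (target_rms / sqrt(mean(x^2)))
  eeg_record(x, spec$fs, class_label = profile$class_label)
}

# per-subject generation parameters: jittered band weights (Dirichlet,
# concentration 100) and log-normal amplitude (sdlog 0.1), all seeded from
# the cohort seed
subject_profile <- function(spec, class_label, i) {
  base <- spec$profiles[[class_label]]
  s0 <- derive_seed(spec$seed, (class_label - 1) * 100000 + i)
  set.seed(s0)
  g <- rgamma(5, shape = 100 * base$band_weights)
  w <- if (sum(g) > 0) g / sum(g) else base$band_weights
  amp <- base$amplitude * rlnorm(1, 0, 0.1)
  list(profile = spectral_profile(class_label, w,
                                  base$pink_noise_fraction, amp),
       subject_seed = derive_seed(s0, 1),
       subject_id = sprintf("sub-%s-%03d",
                            c("MCI", "AD", "HC")[class_label], i))
}

generate_subject <- function(spec, class_label, i) {
  sp <- subject_profile(spec, class_label, i)
  rec <- generate_record(sp$profile, spec, sp$subject_seed)
  rec$subject_id <- sp$subject_id
  rec
}

#' Generate a full three-class cohort
#'
#' Returns `n_per_class` records per class with labels 1/2/3; per-subject
#' band weights are jittered (Dirichlet, concentration 100) and amplitudes
#' log-normally (sdlog 0.1) around the class profile, so classes overlap
#' realistically rather than being point masses. All per-subject seeds derive
#' deterministically from `spec$seed`.
#'
#' Note a default cohort holds 192 records of 19 x 76800 doubles (~2 GB);
#' for feature extraction at scale prefer the streaming [cohort_features()].
#'
#' @param spec A [cohort_spec()].
#' @return List of [eeg_record()] objects, classes in label order.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_per_class = 1, duration = 4))
#' length(cohort)
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  out <- vector("list", 3 * spec$n_per_class)
  k <- 0
  for (cl in 1:3) for (i in seq_len(spec$n_per_class)) {
    k <- k + 1
    out[[k]] <- generate_subject(spec, cl, i)
  }
  out
}

#' Stream a cohort through preprocessing and feature extraction
#'
#' Generates each subject, conditions the record (optional resampling and
#' window cropping) and extracts the seven TD-PSD features, without ever
#' holding more than one record in memory. This is the scale-safe path for
#' the full study geometry (192 records of 300 s).
#'
#' @param spec A [cohort_spec()].
#' @param window A [window_spec()], or `NULL` to skip conditioning.
#' @param lambda,epsilon Feature-extraction parameters, see
#'   [extract_features()].
#' @param aggregation Channel aggregation, see [subject_features()].
#' @return A [feature_table()] of 7 x (3 * n_per_class).
#' @export
#' @examples
#' ft <- cohort_features(cohort_spec(n_per_class = 2, duration = 8),
#'                       window = NULL)
#' dim(ft$matrix)
cohort_features <- function(spec, window = window_spec(), lambda = 0.1,
                            epsilon = 1e-12, aggregation = "mean") {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!identical(aggregation, "mean"))
    stop("cohort_features assembles 7 x N tables; use aggregation = 'mean'")
  n_tot <- 3 * spec$n_per_class
  mat <- matrix(NA_real_, 7, n_tot)
  labels <- integer(n_tot)
  ids <- character(n_tot)
  k <- 0
  for (cl in 1:3) for (i in seq_len(spec$n_per_class)) {
    k <- k + 1
    rec <- generate_subject(spec, cl, i)
    if (!is.null(window)) rec <- preprocess_record(rec, window)
    mat[, k] <- subject_features(rec, aggregation = aggregation,
                                 lambda = lambda, epsilon = epsilon)
    labels[k] <- cl
    ids[k] <- rec$subject_id
  }
  feature_table(mat, labels, ids)
}
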