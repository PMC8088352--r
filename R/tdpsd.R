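# The seven time-dependent power spectrum descriptors (TD-PSD).
#
# By Parseval's theorem the total squared signal equals the integral of the
# phase-excluded power spectrum, and by the Fourier time-differentiation
# property the even spectral moments m2 and m4 are reachable in the time
# domain as sums of squared first and second differences. The seven features
# are log-domain functionals of the lambda-power-transformed root-squared
# moments plus two direct time-domain statistics (coefficient of variation,
# Teager-Kaiser energy).

#' Finite differences of a sample sequence
#'
#' Order 1 returns `x[j] - x[j-1]` (length `N - 1`); order 2 differences
#' twice (length `N - 2`). Each differentiation shortens the sequence by one:
#' sums over differences run over valid indices only.
#'
#' @param x Numeric vector.
#' @param order 1 or 2.
#' @return Numeric vector of differences.
#' @export
#' @examples
#' diff_series(c(1, 2, 4), 1)  # 1 2
diff_series <- function(x, order = 1) {
  stopifnot(order %in% c(1, 2))
  if (length(x) <= order)
    stop("sequence too short for difference order ", order)
  assert_finite(x, "x")
  diff(x, differences = order)
}

#' Root-squared spectral moments from the time domain
#'
#' `m0_bar = sqrt(sum(x^2))`, `m2_bar = sqrt(sum(diff(x)^2))`,
#' `m4_bar = sqrt(sum(diff(x, 2)^2))`. m0 is the square root of the overall
#' spectral power (Parseval); m2 and m4 are the even-moment analogues via
#' time differentiation. Odd moments of the symmetric phase-excluded spectrum
#' vanish and are not computed.
#'
#' @param x Numeric vector, length >= 3, finite.
#' @return Object of class `raw_moments` with fields `m0_bar`, `m2_bar`,
#'   `m4_bar`.
#' @export
#' @examples
#' raw_moments(c(3, 4, 0))$m0_bar  # 5
raw_moments <- function(x) {
  if (length(x) < 3) stop("need at least 3 samples")
  assert_finite(x, "x")
  structure(list(m0_bar = sqrt(sum(x^2)),
                 m2_bar = sqrt(sum(diff_series(x, 1)^2)),
                 m4_bar = sqrt(sum(diff_series(x, 2)^2))),
            class = "raw_moments")
}

#' Lambda power transform of the moments
#'
#' `m = m_bar^lambda / lambda` with `lambda = 0.1` by default; compresses the
#' dynamic range of the moments to damp noise sensitivity. Zero maps to zero;
#' the transform is monotone for nonnegative moments.
#'
#' @param m A [raw_moments()] object.
#' @param lambda Positive exponent.
#' @return Object of class `normalized_moments` with fields `m0`, `m2`,
#'   `m4`, `lambda`.
#' @export
#' @examples
#' power_transform(raw_moments(c(3, 4, 0)))$lambda
power_transform <- function(m, lambda = 0.1) {
  stopifnot(inherits(m, "raw_moments"), lambda > 0)
  vals <- c(m$m0_bar, m$m2_bar, m$m4_bar)
  if (any(vals < 0)) stop("moments must be nonnegative")
  tr <- ifelse(vals == 0, 0, vals^lambda / lambda)
  structure(list(m0 = tr[1], m2 = tr[2], m4 = tr[3], lambda = lambda),
            class = "normalized_moments")
}

#' Extract the seven TD-PSD features from one channel
#'
#' With `m0, m2, m4` the lambda-transformed root-squared moments:
#' \describe{
#'   \item{f1}{`log(m0 + eps)` - transformed total power.}
#'   \item{f2}{`log(|m0 - m2| + eps)`.}
#'   \item{f3}{`log(|m0 - m4| + eps)`.}
#'   \item{f4}{sparseness `log(m0 / (sqrt(|m0 - m2|) * sqrt(|m0 - m4|)))`;
#'     exactly the zero-sparseness index 0 for a constant signal, where
#'     differentiation forces `m2 = m4 = 0`.}
#'   \item{f5}{irregularity factor `log(m2 / sqrt(m0 * m4))` - the ratio of
#'     upward zero crossings to peaks expressed through the moments.}
#'   \item{f6}{coefficient of variation `log(sd(x) / |mean(x)|)` (population
#'     standard deviation).}
#'   \item{f7}{Teager-Kaiser energy
#'     `log(|sum(x[j]^2 - x[j-1] * x[j+1])|)` over the valid interior
#'     indices.}
#' }
#' Every log argument carries an additive guard `eps` (and every ratio a
#' guarded denominator) so all outputs are finite even for degenerate input;
#' an all-zero signal returns the eps-floor values with attribute
#' `degenerate = TRUE`.
#'
#' @param x Numeric vector, length >= 3.
#' @param lambda Power-transform exponent (default 0.1).
#' @param epsilon Log guard (default 1e-12).
#' @return Named numeric vector `f1..f7` with attributes `lambda`, `epsilon`
#'   and `degenerate`.
#' @export
#' @examples
#' extract_features(sin(seq(0, 10, length.out = 256)))
extract_features <- function(x, lambda = 0.1, epsilon = 1e-12) {
  if (length(x) < 3) stop("need at least 3 samples")
  assert_finite(x, "x")
  stopifnot(lambda > 0, epsilon >= 0)
  nm <- power_transform(raw_moments(x), lambda)
  m0 <- nm$m0; m2 <- nm$m2; m4 <- nm$m4
  eps <- epsilon
  n <- length(x)
  mu <- mean(x)
  sd_pop <- sqrt(mean((x - mu)^2))
  teo <- sum(x[2:(n - 1)]^2 - x[1:(n - 2)] * x[3:n])
  f <- c(
    f1 = log(m0 + eps),
    f2 = log(abs(m0 - m2) + eps),
    f3 = log(abs(m0 - m4) + eps),
    f4 = log(m0 / (sqrt(abs(m0 - m2)) * sqrt(abs(m0 - m4)) + eps) + eps),
    f5 = log(m2 / (sqrt(m0 * m4) + eps) + eps),
    f6 = log(sd_pop / (abs(mu) + eps) + eps),
    f7 = log(abs(teo) + eps)
  )
  attr(f, "lambda") <- lambda
  attr(f, "epsilon") <- eps
  attr(f, "degenerate") <- nm$m0 == 0
  f
}

#' Per-subject feature vector from a multichannel record
#'
#' Extracts the seven features on every channel, then either averages each
#' feature across channels (`"mean"`, the default, yielding the study's
#' 7-per-subject shape) or returns the full 7 x n_channels matrix
#' (`"concat"`).
#'
#' @param record An [eeg_record()].
#' @param aggregation `"mean"` or `"concat"`.
#' @param lambda,epsilon See [extract_features()].
#' @return Named length-7 vector (mean) or 7 x n_channels matrix (concat).
#' @export
subject_features <- function(record, aggregation = c("mean", "concat"),
                             lambda = 0.1, epsilon = 1e-12) {
  stopifnot(inherits(record, "eeg_record"))
  aggregation <- match.arg(aggregation)
  per_ch <- apply(record$samples, 1, extract_features,
                  lambda = lambda, epsilon = epsilon)  # 7 x n_channels
  rownames(per_ch) <- paste0("f", 1:7)
  if (aggregation == "mean") rowMeans(per_ch) else per_ch
}

#' Normalize zero-order moments across channels
#'
#' Divides each channel's m0 by the sum over channels so the outputs sum
#' to 1. An optional standardization step; off by default in the pipeline.
#'
#' @param m0 Nonnegative numeric vector of per-channel zero-order moments.
#' @return Vector of the same length summing to 1.
#' @export
#' @examples
#' normalize_m0_across_channels(c(2, 2))  # 0.5 0.5
normalize_m0_across_channels <- function(m0) {
  assert_finite(m0, "m0")
  if (length(m0) < 1 || any(m0 < 0)) stop("m0 must be nonnegative")
  s <- sum(m0)
  if (s <= 0) stop("all-zero m0 vector cannot be normalized")
  m0 / s
}

#' Feature table: 7 x N matrix with class labels
#'
#' @param matrix Numeric 7 x N matrix of features (rows f1..f7).
#' @param labels Integer class labels in `{1, 2, 3}`, one per column.
#' @param subject_ids Optional identifiers, one per column.
#' @return Object of class `feature_table`.
#' @export
feature_table <- function(matrix, labels, subject_ids = NULL) {
  if (!is.matrix(matrix) || nrow(matrix) != 7)
    stop("feature matrix must have 7 rows (f1..f7)")
  if (length(labels) != ncol(matrix))
    stop("labels length must match the number of subjects")
  if (!all(labels %in% 1:3)) stop("labels must be in {1, 2, 3}")
  if (is.null(subject_ids)) subject_ids <- sprintf("S%04d", seq_len(ncol(matrix)))
  if (length(subject_ids) != ncol(matrix))
    stop("subject_ids length must match the number of subjects")
  rownames(matrix) <- paste0("f", 1:7)
  colnames(matrix) <- subject_ids
  structure(list(matrix = matrix, labels = as.integer(labels),
                 subject_ids = subject_ids),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> 7 features x %d subjects (MCI %d, AD %d, HC %d)\n",
              ncol(x$matrix), sum(x$labels == 1), sum(x$labels == 2),
              sum(x$labels == 3)))
  invisible(x)
}

#' Subset a feature table by subject
#'
#' @param ft A [feature_table()].
#' @param idx Column (subject) indices.
#' @return The subsetted [feature_table()].
#' @export
ft_subset <- function(ft, idx) {
  stopifnot(inherits(ft, "feature_table"))
  feature_table(ft$matrix[, idx, drop = FALSE], ft$labels[idx],
                ft$subject_ids[idx])
}

#' @export
as.data.frame.feature_table <- function(x, ...) {
  data.frame(subject_id = x$subject_ids, label = x$labels,
             t(x$matrix), row.names = NULL)
}
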