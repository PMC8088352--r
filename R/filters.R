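# Chebyshev type-I low-pass design and zero-phase filtering.
#
# No DSP package is assumed: the analog prototype poles have a closed form,
# the digital filter follows by the bilinear transform, and zero-phase
# application uses forward-backward filtering with odd-extension padding and
# steady-state initial conditions (the scipy/filtfilt convention).

poly_from_roots <- function(r) {
  p <- complex(real = 1)
  for (rt in r) p <- c(p, 0) - c(0, rt * p)
  p
}

#' Design a digital Chebyshev type-I low-pass filter
#'
#' Closed-form analog prototype (poles on an ellipse determined by the ripple)
#' followed by frequency pre-warping and the bilinear transform.
#'
#' @param order Filter order (number of poles).
#' @param rp_db Pass-band ripple in dB.
#' @param wn Cutoff as a fraction of the Nyquist frequency, in (0, 1).
#' @return List with numerator `b` and denominator `a` coefficients
#'   (`a[1] = 1`).
#' @keywords internal
cheby1_lowpass <- function(order, rp_db, wn) {
  stopifnot(order >= 1, rp_db > 0, wn > 0, wn < 1)
  eps <- sqrt(10^(rp_db / 10) - 1)
  mu <- asinh(1 / eps) / order
  theta <- pi * (2 * seq_len(order) - 1) / (2 * order)
  p <- complex(real = -sinh(mu) * sin(theta), imaginary = cosh(mu) * cos(theta))
  k <- prod(-p)
  if (order %% 2 == 0) k <- k / sqrt(1 + eps^2)

  # low-pass transform to the pre-warped analog cutoff (fs = 2 convention)
  warped <- 4 * tan(pi * wn / 2)
  p <- warped * p
  k <- k * warped^order

  # bilinear transform; analog zeros at infinity map to z = -1
  fs2 <- 4
  pz <- (fs2 + p) / (fs2 - p)
  kz <- Re(k / prod(fs2 - p))
  b <- Re(kz * poly_from_roots(rep(-1 + 0i, order)))
  a <- Re(poly_from_roots(pz))
  list(b = b, a = a / a[1])
}

# Steady-state initial filter state so a step input produces no transient.
lfilter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  b <- c(b, rep(0, n - length(b)))
  a <- c(a, rep(0, n - length(a)))
  if (n == 1) return(numeric(0))
  # companion matrix of a, transposed
  A <- matrix(0, n - 1, n - 1)
  A[1, ] <- -a[2:n] / a[1]
  if (n > 2) A[cbind(2:(n - 1), 1:(n - 2))] <- 1
  B <- b[2:n] - a[2:n] * b[1]
  solve(diag(n - 1) - t(A), B)
}

#' Zero-phase IIR filtering
#'
#' Applies the filter forward and backward with odd-extension padding of
#' length `3 * max(length(a), length(b))` and steady-state initial
#' conditions, so the result has no phase distortion and minimal edge
#' transients.
#'
#' @param b,a Filter coefficients.
#' @param x Numeric vector to filter.
#' @return Filtered vector of the same length as `x`.
#' @keywords internal
filtfilt_iir <- function(b, a, x) {
  n <- length(x)
  padlen <- 3 * max(length(a), length(b))
  if (n <= padlen) stop("signal too short for filtfilt padding")
  ext <- c(2 * x[1] - x[(padlen + 1):2], x, 2 * x[n] - x[(n - 1):(n - padlen)])
  zi <- lfilter_zi(b, a)
  y <- lfilter_cpp(b, a, ext, zi * ext[1])
  y <- rev(y)
  y <- lfilter_cpp(b, a, y, zi * y[1])
  y <- rev(y)
  y[(padlen + 1):(padlen + n)]
}
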