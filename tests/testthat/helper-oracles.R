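# Independent reference implementations used as oracles. Deliberately
# written in plain loop / textbook form, not sharing code paths with the
# package internals they check.

# literal transcription of the seven-descriptor formulas
oracle_tdpsd <- function(x, lambda = 0.1, eps = 1e-12) {
  n <- length(x)
  d1 <- numeric(n - 1)
  for (j in 2:n) d1[j - 1] <- x[j] - x[j - 1]
  d2 <- numeric(n - 2)
  for (j in 2:(n - 1)) d2[j - 1] <- d1[j] - d1[j - 1]
  sq <- function(v) { s <- 0; for (vi in v) s <- s + vi * vi; sqrt(s) }
  m0b <- sq(x); m2b <- sq(d1); m4b <- sq(d2)
  pt <- function(mb) if (mb == 0) 0 else mb^lambda / lambda
  m0 <- pt(m0b); m2 <- pt(m2b); m4 <- pt(m4b)
  mu <- sum(x) / n
  sdp <- sqrt(sum((x - mu)^2) / n)
  teo <- 0
  for (j in 2:(n - 1)) teo <- teo + x[j]^2 - x[j - 1] * x[j + 1]
  c(f1 = log(m0 + eps),
    f2 = log(abs(m0 - m2) + eps),
    f3 = log(abs(m0 - m4) + eps),
    f4 = log(m0 / (sqrt(abs(m0 - m2)) * sqrt(abs(m0 - m4)) + eps) + eps),
    f5 = log(m2 / (sqrt(m0 * m4) + eps) + eps),
    f6 = log(sdp / (abs(mu) + eps) + eps),
    f7 = log(abs(teo) + eps))
}

# Parseval right-hand side: (1/N) * sum |X[k]|^2 from the FFT
oracle_fft_power <- function(x) sum(Mod(stats::fft(x))^2) / length(x)

# Welch PSD with a Hann window, 50% overlap; returns one-sided freq/psd
oracle_welch <- function(x, fs, seg_len = 1024) {
  hop <- seg_len %/% 2
  win <- 0.5 - 0.5 * cos(2 * pi * seq(0, seg_len - 1) / seg_len)
  u <- sum(win^2)
  starts <- seq(1, length(x) - seg_len + 1, by = hop)
  acc <- numeric(seg_len)
  for (s in starts) {
    seg <- (x[s:(s + seg_len - 1)] - mean(x[s:(s + seg_len - 1)])) * win
    acc <- acc + Mod(stats::fft(seg))^2 / u
  }
  psd <- acc / length(starts)
  half <- seg_len %/% 2
  list(freq = (0:(half - 1)) * fs / seg_len, psd = psd[1:half])
}

# fraction of Welch power inside each EEG band (relative to all-band total)
oracle_band_fractions <- function(x, fs, seg_len = 1024) {
  w <- oracle_welch(x, fs, seg_len)
  bands <- matrix(c(0.1, 4, 4, 8, 8, 12, 12, 30, 30, 45), ncol = 2,
                  byrow = TRUE)
  frac <- apply(bands, 1, function(b)
    sum(w$psd[w$freq >= b[1] & w$freq < b[2]]))
  frac / sum(frac)
}

# AUC as the normalized Mann-Whitney U statistic (pairwise counting)
oracle_mw_auc <- function(score, positive) {
  sp <- score[positive]; sn <- score[!positive]
  tot <- 0
  for (a in sp) for (b in sn) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# three well-separated Gaussian clouds in feature space (subjects x 7 -> ft)
make_cloud_ft <- function(n_per_class = 30, sep = 3, sd = 0.3, seed = 1) {
  set.seed(seed)
  centers <- list(rep(0, 7), rep(sep, 7), rep(-sep, 7))
  X <- do.call(rbind, lapply(centers, function(ctr)
    matrix(stats::rnorm(7 * n_per_class, 0, sd), n_per_class, 7) +
      rep(ctr, each = n_per_class)))
  feature_table(t(X), rep(1:3, each = n_per_class))
}
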