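# The seven-descriptor feature core.

test_that("difference series follow the definition", {
  expect_equal(diff_series(c(1, 2, 4), 1), c(1, 2))
  expect_equal(diff_series(rep(5, 10), 1), rep(0, 9))
  expect_equal(diff_series(rep(5, 10), 2), rep(0, 8))
  expect_equal(diff_series(seq(2, 20, by = 2), 2), rep(0, 8))
  expect_error(diff_series(c(1, 2), 2), "too short")
  expect_error(diff_series(c(1, NA, 3), 1), "finite")
})

test_that("raw moments: 3-4-5, constant signals, and Parseval vs FFT oracle", {
  expect_equal(raw_moments(c(3, 4, 0))$m0_bar, 5)
  m <- raw_moments(rep(2.5, 50))
  expect_equal(m$m2_bar, 0)
  expect_equal(m$m4_bar, 0)
  # Parseval: sum x^2 == (1/N) sum |X[k]|^2, 100 random signals
  set.seed(101)
  for (i in 1:100) {
    n <- sample(16:1024, 1)
    x <- rnorm(n)
    expect_equal(raw_moments(x)$m0_bar^2, oracle_fft_power(x),
                 tolerance = 1e-9)
  }
  expect_error(raw_moments(c(1, 2)), "at least 3")
})

test_that("power transform compresses as m^lambda / lambda", {
  rm1 <- structure(list(m0_bar = 1, m2_bar = 0, m4_bar = 1024),
                   class = "raw_moments")
  nm <- power_transform(rm1, lambda = 0.1)
  expect_equal(nm$m0, 10)         # 1^0.1 / 0.1
  expect_equal(nm$m2, 0)          # zero maps to zero
  expect_equal(nm$m4, 20)         # 1024^0.1 / 0.1 = 2 * 10
  expect_error(power_transform(rm1, lambda = 0))
})

test_that("extract_features matches the literal-formula oracle", {
  x <- c(1, 2, 3, 4, 3, 2, 1, 0)
  expect_equal(unname(extract_features(x)[1:7]), unname(oracle_tdpsd(x)),
               tolerance = 1e-9, ignore_attr = TRUE)
  set.seed(202)
  for (i in 1:1000) {
    n <- sample(c(8, 16, 64, 256, 500), 1)
    x <- rnorm(n, sd = runif(1, 0.1, 10))
    expect_equal(as.numeric(extract_features(x)), unname(oracle_tdpsd(x)),
                 tolerance = 1e-9)
  }
})

test_that("constant signal has zero sparseness and zero even moments", {
  f <- extract_features(rep(3, 100))
  expect_equal(unname(f["f4"]), 0, tolerance = 1e-9)
  expect_false(attr(f, "degenerate"))
  # all-zero signal: finite eps-floor values, flagged
  f0 <- extract_features(rep(0, 100))
  expect_true(all(is.finite(f0)))
  expect_true(attr(f0, "degenerate"))
})

test_that("scale behavior: f4-f6 invariant, f1-f3 shift by lambda*log(c)", {
  set.seed(303)
  lambda <- 0.1
  for (i in 1:20) {
    x <- rnorm(256)
    cc <- runif(1, 0.5, 20)
    f <- extract_features(x, lambda = lambda)
    fc <- extract_features(cc * x, lambda = lambda)
    expect_equal(unname(fc[c("f4", "f5", "f6")]),
                 unname(f[c("f4", "f5", "f6")]), tolerance = 1e-9)
    shift <- unname(fc[c("f1", "f2", "f3")] - f[c("f1", "f2", "f3")])
    expect_equal(shift, rep(lambda * log(cc), 3), tolerance = 1e-6)
  }
})

test_that("high-frequency content raises m2/m0 monotonically", {
  set.seed(404)
  base <- rnorm(512)
  pert <- rep(c(1, -1), length.out = 512)
  ratios <- vapply(c(0, 0.5, 1, 2, 4), function(a) {
    m <- raw_moments(base + a * pert)
    m$m2_bar / m$m0_bar
  }, numeric(1))
  expect_true(all(diff(ratios) > 0))
})

test_that("subject aggregation: mean over channels, concat shape", {
  set.seed(505)
  x <- rnorm(512)
  rec1 <- eeg_record(matrix(x, 1), fs = 256)
  expect_equal(subject_features(rec1, "mean"), extract_features(x)[1:7],
               ignore_attr = TRUE)
  rec19 <- eeg_record(matrix(rep(x, 19), 19, byrow = TRUE), fs = 256)
  expect_equal(subject_features(rec19, "mean"), extract_features(x)[1:7],
               ignore_attr = TRUE)
  expect_equal(dim(subject_features(rec19, "concat")), c(7, 19))
})

test_that("m0 cross-channel normalization sums to one", {
  expect_equal(normalize_m0_across_channels(c(2, 2)), c(0.5, 0.5))
  expect_equal(normalize_m0_across_channels(7), 1)
  set.seed(606)
  v <- runif(19, 0.01, 5)
  expect_equal(sum(normalize_m0_across_channels(v)), 1, tolerance = 1e-12)
  expect_error(normalize_m0_across_channels(rep(0, 3)), "all-zero")
})

test_that("feature tables validate their shape and labels", {
  m <- matrix(rnorm(21), 7, 3)
  ft <- feature_table(m, c(1, 2, 3))
  expect_equal(ncol(ft$matrix), 3)
  expect_error(feature_table(m[1:6, ], c(1, 2, 3)), "7 rows")
  expect_error(feature_table(m, c(1, 2)), "length")
  expect_error(feature_table(m, c(1, 2, 4)), "labels")
  df <- as.data.frame(ft)
  expect_equal(dim(df), c(3, 9))
})
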