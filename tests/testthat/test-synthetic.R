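# Synthetic cohort generator: determinism, geometry, spectral contract.

small_spec <- function(seed = 3, n_per_class = 2, duration = 10,
                       n_channels = 4, fs = 256)
  cohort_spec(n_per_class = n_per_class, n_channels = n_channels,
              duration = duration, fs = fs, seed = seed)

test_that("profiles validate weights and orderings", {
  expect_error(spectral_profile(1, c(0.5, 0.5, 0.1, 0, 0)), "sum to 1")
  expect_error(spectral_profile(1, c(0.6, 0.5, -0.1, 0, 0)), "nonnegative")
  p <- default_profiles()
  slow <- vapply(p, function(x) sum(x$band_weights[c("delta", "theta")]),
                 numeric(1))
  expect_true(slow["AD"] > slow["MCI"] && slow["MCI"] > slow["HC"])
  expect_true(p$HC$band_weights["alpha"] > p$AD$band_weights["alpha"])
  for (pr in p) expect_equal(sum(pr$band_weights), 1, tolerance = 1e-9)
})

test_that("records are deterministic, correctly shaped, finite", {
  spec <- small_spec()
  r1 <- generate_record(default_profiles()$AD, spec, 42)
  r2 <- generate_record(default_profiles()$AD, spec, 42)
  expect_identical(r1$samples, r2$samples)
  expect_equal(dim(r1$samples), c(4, 2560))
  expect_true(all(is.finite(r1$samples)))
  r3 <- generate_record(default_profiles()$AD, spec, 43)
  expect_false(identical(r1$samples, r3$samples))
  # band edges must stay below Nyquist
  expect_error(generate_record(default_profiles()$AD,
                               small_spec(fs = 64, duration = 16), 1),
               "Nyquist")
})

test_that("cohorts have the stated size, labels and seed contract", {
  co <- generate_cohort(small_spec(n_per_class = 1, duration = 5))
  expect_length(co, 3)
  expect_equal(vapply(co, `[[`, integer(1), "class_label"), 1:3)
  a <- generate_cohort(small_spec(seed = 1, duration = 5))
  b <- generate_cohort(small_spec(seed = 1, duration = 5))
  d <- generate_cohort(small_spec(seed = 2, duration = 5))
  expect_identical(lapply(a, `[[`, "samples"), lapply(b, `[[`, "samples"))
  expect_false(identical(a[[1]]$samples, d[[1]]$samples))
  expect_identical(dim(a[[1]]$samples), dim(d[[1]]$samples))
})

test_that("spectral contract: Welch band fractions track the profile", {
  # 20 records per class (scaled to 30 s, 2 channels to stay in budget),
  # averaged band fractions within +-0.1 of the stated weights
  spec <- cohort_spec(n_per_class = 20, n_channels = 2, duration = 30,
                      fs = 256, seed = 77)
  prof <- default_profiles()
  slow_alpha <- list()
  for (cl in c(2, 3)) {   # AD and HC
    fr <- rowMeans(vapply(seq_len(20), function(i) {
      rec <- tdpsd:::generate_subject(spec, cl, i)
      rowMeans(apply(rec$samples, 1, oracle_band_fractions, fs = 256))
    }, numeric(5)))
    expect_lt(max(abs(fr - prof[[c("MCI", "AD", "HC")[cl]]]$band_weights)),
              0.1)
    slow_alpha[[as.character(cl)]] <- (fr[1] + fr[2]) / fr[3]
  }
  # EEG slowing: (delta+theta)/alpha strictly greater for AD than HC
  expect_gt(slow_alpha[["2"]], slow_alpha[["3"]])
})

test_that("f1 separates AD from HC by >2 pooled SD at n = 64", {
  # study geometry n = 64/class; duration scaled to 60 s (the separation is
  # carried by amplitude factors and band weights, not record length)
  spec <- cohort_spec(n_per_class = 64, duration = 60, seed = 5)
  ft <- cohort_features(spec, window = window_spec(5, 55, 256))
  f1_ad <- ft$matrix[1, ft$labels == 2]
  f1_hc <- ft$matrix[1, ft$labels == 3]
  pooled <- sqrt((var(f1_ad) + var(f1_hc)) / 2)
  expect_gt(abs(mean(f1_ad) - mean(f1_hc)), 2 * pooled)
})

test_that("cohort_features streams to a labelled 7 x N table", {
  ft <- cohort_features(small_spec(duration = 8), window = NULL)
  expect_s3_class(ft, "feature_table")
  expect_equal(dim(ft$matrix), c(7, 6))
  expect_equal(ft$labels, rep(1:3, each = 2))
  expect_true(all(is.finite(ft$matrix)))
})
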