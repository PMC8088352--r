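# Split, activation primitives, and the four classifiers.

test_that("stratified split: study geometry 192 -> 153/39, deterministic", {
  ft <- make_cloud_ft(64, seed = 21)
  sp <- split_data(ft, split_spec(0.8, seed = 5))
  expect_equal(length(sp$train$labels), 153)   # 3 * floor(0.8 * 64) = 3 * 51
  expect_equal(length(sp$test$labels), 39)
  expect_equal(as.numeric(table(sp$train$labels)), rep(51, 3))
  expect_equal(as.numeric(table(sp$test$labels)), rep(13, 3))
  # disjoint and exhaustive
  expect_equal(sort(c(sp$train$subject_ids, sp$test$subject_ids)),
               sort(ft$subject_ids))
  sp2 <- split_data(ft, split_spec(0.8, seed = 5))
  expect_identical(sp$train$subject_ids, sp2$train$subject_ids)
  sp3 <- split_data(ft, split_spec(0.8, seed = 6))
  expect_false(identical(sp$train$subject_ids, sp3$train$subject_ids))
  # class with one subject cannot be stratified
  tiny <- feature_table(matrix(rnorm(7 * 5), 7), c(1, 1, 2, 2, 3))
  expect_error(split_data(tiny, split_spec(0.8)), "at least 2")
  expect_error(split_spec(1), "train_fraction")
})

test_that("relu and softmax primitives", {
  expect_equal(relu(-2), 0)
  expect_equal(relu(0), 0)
  expect_equal(relu(3.5), 3.5)
  v <- c(-1.5, 0, 2, -0.1)
  expect_equal(relu(relu(v)), relu(v))
  expect_equal(softmax(c(0, 0, 0)), rep(1 / 3, 3))
  expect_equal(softmax(c(7, 7 + 2, 7)), softmax(c(0, 2, 0)))
  s <- softmax(c(1, 2, 3))
  expect_equal(s, exp(c(1, 2, 3)) / sum(exp(c(1, 2, 3))))
  expect_equal(sum(s), 1)
  m <- softmax(matrix(c(1000, 1001, 999, -5, 0, 5), 2, byrow = TRUE))
  expect_equal(rowSums(m), c(1, 1))
})

test_that("all classifiers solve three separated clouds perfectly", {
  ft <- make_cloud_ft(30, sep = 3, sd = 0.3, seed = 9)
  for (kind in c("knn", "svm", "lda")) {
    m <- train_classical(kind, ft)
    p <- predict(m, ft)
    expect_equal(mean(p$labels == ft$labels), 1)
    expect_equal(rowSums(p$scores), rep(1, 90), tolerance = 1e-9)
    # argmax consistency: the reported label always attains the row max
    expect_true(all(p$scores[cbind(seq_len(90), p$labels)] ==
                      apply(p$scores, 1, max)))
  }
})

test_that("KNN with k = 1 reproduces its training labels", {
  ft <- make_cloud_ft(15, sep = 1, sd = 0.8, seed = 10)
  m <- train_classical("knn", ft, hyperparams = list(k = 1))
  p <- predict(m, ft)
  expect_equal(p$labels, ft$labels)
})

test_that("LDA boundary sits at the midpoint of two isotropic Gaussians", {
  set.seed(31)
  n <- 400
  mu1 <- c(2, rep(0, 6)); mu2 <- c(-2, rep(0, 6))
  X <- rbind(matrix(rnorm(7 * n), n, 7) + rep(mu1, each = n),
             matrix(rnorm(7 * n), n, 7) + rep(mu2, each = n))
  ft <- feature_table(t(X), rep(c(1, 2), each = n))
  m <- suppressWarnings(train_classical("lda", ft))  # class 3 absent, by design
  mid <- (mu1 + mu2) / 2
  p_mid <- predict(m, matrix(mid, 1))$scores[1, 1:2]
  expect_equal(unname(p_mid[1]), 0.5, tolerance = 0.1)
  # points clearly on either side classify by side
  expect_equal(predict(m, matrix(mid + c(1, rep(0, 6)), 1))$labels, 1L)
  expect_equal(predict(m, matrix(mid - c(1, rep(0, 6)), 1))$labels, 2L)
})

test_that("prediction validates the feature dimension", {
  ft <- make_cloud_ft(10, seed = 12)
  m <- train_classical("knn", ft)
  expect_error(predict(m, matrix(rnorm(6), 1)), "dimension")
})

test_that("synthetic benchmark: >=0.80 held-out accuracy, CNN >= SVM/LDA", {
  # study geometry 64/class over 5 seeds; record duration scaled to 60 s
  # (class separation is spectral, not duration-dependent) to stay in budget
  accs <- sapply(1:5, function(seed) {
    spec <- cohort_spec(n_per_class = 64, duration = 60, seed = seed)
    ft <- cohort_features(spec, window = window_spec(5, 55, 256))
    sp <- split_data(ft, split_spec(0.8, seed = derive_seed(seed, 11)))
    out <- c()
    for (kind in c("knn", "svm", "lda")) {
      m <- suppressWarnings(train_classical(kind, sp$train))
      out[kind] <- mean(predict(m, sp$test)$labels == sp$test$labels)
    }
    mc <- build_and_train_cnn(sp$train,
                              cnn_config(seed = derive_seed(seed, 14)))
    out["cnn"] <- mean(predict(mc, sp$test)$labels == sp$test$labels)
    out
  })
  # per-classifier median over the 5 seeds; the CNN must match or beat the
  # better of the SVM and LDA medians
  med <- apply(accs, 1, median)
  expect_true(all(med >= 0.80))
  expect_gte(med["cnn"], max(med["svm"], med["lda"]))
})
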