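# Confusion matrix, per-class metrics, ROC/AUC, summary report.

round_half_up <- tdpsd:::round_half_up

test_that("confusion matrix counts match an independent tally", {
  cm <- confusion_matrix3(c(1, 2, 3), c(1, 2, 3))
  expect_equal(diag(cm$counts), c(MCI = 1, AD = 1, HC = 1))
  expect_equal(accuracy(cm), 1)
  cm1 <- confusion_matrix3(1, 2)
  expect_equal(cm1$counts["MCI", "AD"], 1)
  expect_equal(sum(cm1$counts), 1)
  set.seed(51)
  yt <- sample(1:3, 300, replace = TRUE)
  yp <- sample(1:3, 300, replace = TRUE)
  cm <- confusion_matrix3(yt, yp)
  for (i in 1:3) for (j in 1:3) {
    tally <- 0
    for (k in seq_along(yt)) if (yt[k] == i && yp[k] == j) tally <- tally + 1
    expect_equal(unname(cm$counts[i, j]), tally)
  }
  expect_equal(sum(cm$counts), 300)
  expect_error(confusion_matrix3(c(1, 4), c(1, 1)), "labels")
  expect_error(confusion_matrix3(c(1, 2), 1), "equal length")
})

test_that("sensitivity, precision, accuracy worked examples", {
  # the study's KNN diagonal: 51/64 MCI, 46/64 AD, 40/64 HC
  y_true <- rep(1:3, each = 64)
  y_pred <- c(rep(1, 51), rep(2, 7), rep(3, 6),
              rep(2, 46), rep(1, 10), rep(3, 8),
              rep(3, 40), rep(1, 12), rep(2, 12))
  cm <- confusion_matrix3(y_true, y_pred)
  expect_equal(round_half_up(100 * sensitivity(cm, 1)), 79.7)  # 51/64
  expect_equal(round_half_up(100 * sensitivity(cm, 2)), 71.9)  # 46/64
  expect_equal(round_half_up(100 * sensitivity(cm, 3)), 62.5)  # 40/64
  expect_equal(round_half_up(100 * accuracy(cm)), 71.4)        # 137/192
  # precision is column arithmetic: a column [51, 20, 9] gives 51/80
  cmp <- structure(list(counts = matrix(c(51, 20, 9, 0, 30, 0, 0, 0, 40),
                                        3, 3,
                                        dimnames = list(
                                          true = c("MCI", "AD", "HC"),
                                          pred = c("MCI", "AD", "HC"))),
                        n = 150), class = "confusion_matrix3")
  expect_equal(precision(cmp, 1), 51 / 80)
  expect_equal(round_half_up(100 * precision(cmp, 1)), 63.7)
  # degenerate cases
  diag3 <- confusion_matrix3(rep(1:3, 2), rep(1:3, 2))
  for (cl in 1:3) {
    expect_equal(sensitivity(diag3, cl), 1)
    expect_equal(precision(diag3, cl), 1)
  }
  off <- confusion_matrix3(1, 2)
  expect_equal(precision(off, 2), 0)        # single off-diagonal entry
  expect_error(sensitivity(off, 3), "undefined")
  expect_error(precision(off, 3), "undefined")
  allwrong <- confusion_matrix3(c(1, 2), c(2, 1))
  expect_equal(accuracy(allwrong), 0)
})

test_that("uniform random predictions give chance accuracy", {
  set.seed(52)
  yt <- sample(1:3, 3000, replace = TRUE)
  yp <- sample(1:3, 3000, replace = TRUE)
  expect_equal(accuracy(confusion_matrix3(yt, yp)), 1 / 3, tolerance = 0.1)
})

test_that("ROC: perfect, null, and rank-sum oracle equivalence", {
  y <- rep(1:3, each = 20)
  s <- matrix(0.1, 60, 3)
  s[cbind(1:60, y)] <- 0.8
  s <- s / rowSums(s)
  expect_equal(roc_one_vs_rest(y, s, 1)$auc, 1)
  r <- roc_one_vs_rest(y, s, 2)
  expect_true(all(diff(r$fpr) >= 0) && all(diff(r$tpr) >= 0))
  expect_equal(range(c(r$fpr, r$tpr)), c(0, 1))
  # label-independent scores -> AUC ~ 0.5
  set.seed(53)
  y2 <- sample(1:3, 1000, replace = TRUE)
  s2 <- matrix(runif(3000), 1000, 3)
  s2 <- s2 / rowSums(s2)
  expect_equal(roc_one_vs_rest(y2, s2, 1)$auc, 0.5, tolerance = 0.05)
  # AUC == normalized Mann-Whitney U on 50 random instances (with ties)
  for (i in 1:50) {
    n <- sample(10:60, 1)
    y3 <- sample(1:3, n, replace = TRUE)
    if (length(unique(y3)) < 2) next
    s3 <- matrix(sample(seq(0, 1, 0.1), 3 * n, replace = TRUE) + 0.05, n, 3)
    s3 <- s3 / rowSums(s3)
    cl <- sample(unique(y3), 1)
    if (all(y3 == cl) || !any(y3 == cl)) next
    expect_equal(roc_one_vs_rest(y3, s3, cl)$auc,
                 oracle_mw_auc(s3[, cl], y3 == cl), tolerance = 1e-9)
  }
  expect_error(roc_one_vs_rest(rep(1, 5), matrix(1 / 3, 5, 3), 1),
               "degenerate")
  expect_error(roc_one_vs_rest(c(1, 2), matrix(1, 2, 3), 1), "sum to 1")
})

test_that("summary report identities", {
  y <- rep(1:3, each = 10)
  s <- matrix(0.1, 30, 3); s[cbind(1:30, y)] <- 0.8; s <- s / rowSums(s)
  rep_ <- evaluate_predictions(y, list(labels = y, scores = s), "toy")
  expect_equal(unname(rep_$sensitivity_pct), rep(100, 3))
  expect_equal(unname(rep_$precision_pct), rep(100, 3))
  expect_equal(rep_$accuracy_pct, 100)
  expect_equal(unname(rep_$auc), rep(1, 3))
  expect_equal(rep_$macro_auc, 1)
  # miss = 100 - sensitivity; accuracy = weighted sensitivity
  set.seed(54)
  yt <- sample(1:3, 200, replace = TRUE)
  yp <- sample(1:3, 200, replace = TRUE)
  cm <- confusion_matrix3(yt, yp)
  r2 <- summarize_performance(cm, NULL, "rand")
  expect_equal(r2$miss_rate_pct, 100 - r2$sensitivity_pct,
               ignore_attr = TRUE)
  w_acc <- sum(vapply(1:3, function(cl)
    sensitivity(cm, cl) * sum(cm$counts[cl, ]) / cm$n, numeric(1)))
  expect_equal(accuracy(cm), w_acc)
  df <- as.data.frame(r2)
  expect_equal(nrow(df), 1)
  expect_true(all(c("sens_mci", "prec_hc", "accuracy") %in% names(df)))
})
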