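# Classical classifiers on the 7-feature vectors: stratified 80/20 split,
# KNN (hand-rolled: per-class vote fractions are part of the model
# contract), LDA via MASS with a shrinkage fallback, and the RBF-SVM in
# svm.R. All training is seed-reproducible.

#' Train/test split specification
#'
#' @param train_fraction Fraction of each class assigned to training
#'   (default 0.8; per-class training count is `floor(fraction * n)`).
#' @param stratified Stratify by class (default `TRUE`; the only supported
#'   mode for three-class tables).
#' @param seed Integer seed controlling membership.
#' @return Object of class `split_spec`.
#' @export
split_spec <- function(train_fraction = 0.8, stratified = TRUE, seed = 1) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  structure(list(train_fraction = train_fraction, stratified = stratified,
                 seed = as.integer(seed)),
            class = "split_spec")
}

#' Stratified train/test split of a feature table
#'
#' Disjoint and exhaustive; per class, `floor(train_fraction * n_class)`
#' subjects go to training (64 subjects at 0.8 give the study's 51/13
#' split). Deterministic given `spec$seed`.
#'
#' @param ft A [feature_table()].
#' @param spec A [split_spec()].
#' @return List with elements `train` and `test`, both [feature_table()]s.
#' @export
split_data <- function(ft, spec = split_spec()) {
  stopifnot(inherits(ft, "feature_table"), inherits(spec, "split_spec"))
  if (!spec$stratified) stop("only stratified splitting is supported")
  counts <- table(factor(ft$labels, levels = 1:3))
  if (any(counts < 2))
    stop("stratification requires at least 2 subjects per class")
  train_idx <- integer(0)
  for (cl in 1:3) {
    idx <- which(ft$labels == cl)
    n_tr <- floor(spec$train_fraction * length(idx))
    set.seed(derive_seed(spec$seed, cl))
    train_idx <- c(train_idx, sample(idx, n_tr))
  }
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_along(ft$labels), train_idx)
  list(train = ft_subset(ft, train_idx), test = ft_subset(ft, test_idx))
}

#' Rectified linear unit
#'
#' Elementwise `max(x, 0)`.
#'
#' @param x Finite numeric vector/matrix.
#' @return Same shape as `x`.
#' @export
#' @examples
#' relu(c(-2, 0, 3.5))
relu <- function(x) {
  assert_finite(x, "x")
  pmax(x, 0)
}

#' Softmax over class scores
#'
#' `exp(x_i) / sum(exp(x_j))`, computed with max-subtraction for numerical
#' stability; invariant under adding a constant to all scores. For a matrix,
#' applied row-wise.
#'
#' @param scores Numeric vector, or matrix with one score row per case.
#' @return Probabilities of the same shape, each (row) summing to 1.
#' @export
#' @examples
#' softmax(c(0, 0, 0))
softmax <- function(scores) {
  assert_finite(scores, "scores")
  if (is.matrix(scores)) {
    z <- exp(scores - apply(scores, 1, max))
    z / rowSums(z)
  } else {
    z <- exp(scores - max(scores))
    z / sum(z)
  }
}

# z-score scaler fit on training data (scale-sensitive methods need a
# declared convention; LDA is affine-invariant and skips it)
fit_scaler <- function(X) {
  mu <- colMeans(X)
  s <- apply(X, 2, sd)
  s[s == 0 | !is.finite(s)] <- 1
  list(mean = mu, sd = s)
}
apply_scaler <- function(scaler, X)
  sweep(sweep(X, 2, scaler$mean), 2, scaler$sd, "/")

ft_x <- function(ft) t(ft$matrix)  # subjects x features

#' Train a classical classifier
#'
#' @param kind `"knn"`, `"svm"` or `"lda"`.
#' @param train Training [feature_table()].
#' @param hyperparams Optional list: `k` (KNN, default 5), `cost` and
#'   `gamma` (SVM, defaults 1 and 1/7), `shrinkage` (LDA fallback ridge,
#'   default 1e-4).
#' @param seed Integer seed recorded in the model metadata (training of
#'   these three methods is itself deterministic).
#' @return Object of class `tdpsd_model` emitting labels and 3-way scores
#'   via [predict()]: KNN neighbor-vote fractions, SVM pairwise-coupled
#'   probabilities, LDA posteriors.
#' @export
train_classical <- function(kind = c("knn", "svm", "lda"), train,
                            hyperparams = list(), seed = 1) {
  kind <- match.arg(kind)
  stopifnot(inherits(train, "feature_table"))
  if (length(unique(train$labels)) < 2)
    stop("training data must contain at least 2 classes")
  X <- ft_x(train)
  y <- train$labels
  fit <- switch(kind,
    knn = {
      scaler <- fit_scaler(X)
      list(X = apply_scaler(scaler, X), y = y, k = hyperparams$k %||% 5,
           scaler = scaler)
    },
    svm = {
      scaler <- fit_scaler(X)
      list(fit = svm_train_multiclass(apply_scaler(scaler, X), y,
                                      cost = hyperparams$cost %||% 1,
                                      gamma = hyperparams$gamma %||% (1 / ncol(X))),
           scaler = scaler)
    },
    lda = {
      fit <- tryCatch(
        MASS::lda(X, grouping = factor(y, levels = 1:3)),
        error = function(e) {
          warning("LDA covariance singular; falling back to shrinkage LDA")
          shrinkage_lda(X, y, gamma = hyperparams$shrinkage %||% 1e-4)
        })
      list(fit = fit)
    })
  structure(list(kind = kind, fit = fit, classes = 1:3,
                 meta = list(seed = seed, hyperparams = hyperparams)),
            class = "tdpsd_model")
}

# pooled-covariance Gaussian discriminant with a ridge on the covariance;
# used only when MASS::lda refuses a singular fit
shrinkage_lda <- function(X, y, gamma = 1e-4) {
  classes <- sort(unique(y))
  mus <- t(vapply(classes, function(cl) colMeans(X[y == cl, , drop = FALSE]),
                  numeric(ncol(X))))
  S <- matrix(0, ncol(X), ncol(X))
  for (cl in classes) {
    Xi <- X[y == cl, , drop = FALSE]
    S <- S + crossprod(sweep(Xi, 2, colMeans(Xi)))
  }
  S <- S / (nrow(X) - length(classes))
  S <- S + gamma * mean(diag(S)) * diag(ncol(X))
  structure(list(classes = classes, means = mus, Sinv = solve(S),
                 prior = as.numeric(table(factor(y, levels = classes))) / length(y)),
            class = "shrinkage_lda")
}

predict_shrinkage_lda <- function(fit, X) {
  disc <- vapply(seq_along(fit$classes), function(i) {
    mu <- fit$means[i, ]
    drop(X %*% (fit$Sinv %*% mu)) - 0.5 * drop(mu %*% fit$Sinv %*% mu) +
      log(fit$prior[i])
  }, numeric(nrow(X)))
  if (is.null(dim(disc))) disc <- matrix(disc, nrow = 1)
  softmax(disc)
}

knn_scores <- function(fit, X) {
  scores <- matrix(0, nrow(X), 3)
  labels <- integer(nrow(X))
  for (i in seq_len(nrow(X))) {
    d <- sqrt(colSums((t(fit$X) - X[i, ])^2))
    ord <- order(d, seq_along(d))        # index tie-break: deterministic
    nb <- ord[seq_len(min(fit$k, length(d)))]
    votes <- tabulate(fit$y[nb], nbins = 3)
    scores[i, ] <- votes / sum(votes)
    top <- which(votes == max(votes))
    if (length(top) > 1) {
      # tie: closest mean distance among the tied classes, then lowest label
      md <- vapply(top, function(cl) mean(d[nb[fit$y[nb] == cl]]), numeric(1))
      top <- top[order(md, top)]
    }
    labels[i] <- top[1]
  }
  list(labels = labels, scores = scores)
}

#' Predict labels and class probabilities
#'
#' @param object A `tdpsd_model` from [train_classical()] or
#'   [build_and_train_cnn()].
#' @param newdata A [feature_table()] or a subjects x 7 numeric matrix.
#' @param ... Unused.
#' @return List with `labels` (integer vector) and `scores` (N x 3 matrix,
#'   rows summing to 1; `argmax` of each row equals the label).
#' @export
predict.tdpsd_model <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "feature_table")) ft_x(newdata)
       else as.matrix(newdata)
  if (ncol(X) != 7) stop("feature dimension mismatch: expected 7 features")
  out <- switch(object$kind,
    knn = knn_scores(object$fit, apply_scaler(object$fit$scaler, X)),
    svm = svm_predict_multiclass(object$fit$fit,
                                 apply_scaler(object$fit$scaler, X)),
    lda = {
      p <- if (inherits(object$fit$fit, "shrinkage_lda"))
        predict_shrinkage_lda(object$fit$fit, X)
      else {
        post <- predict(object$fit$fit, X)$posterior
        full <- matrix(0, nrow(X), 3)
        full[, as.integer(colnames(post))] <- post
        full
      }
      list(labels = max.col(p, ties.method = "first"), scores = p)
    },
    cnn = cnn_predict(object$fit, X))
  colnames(out$scores) <- c("MCI", "AD", "HC")
  out$labels <- as.integer(out$labels)
  out
}
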