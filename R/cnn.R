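# A small 1-D convolutional network for the 7-feature vectors, implemented
# directly (no deep-learning framework is available in the target
# environment): conv -> batch-norm -> ReLU -> max-pool -> conv -> batch-norm
# -> ReLU -> fully-connected -> dropout -> fully-connected -> softmax,
# trained with cross-entropy and Adam. The 7 x 1 input admits pooling only
# along the length axis, so the pool is 2 x 1 with stride 2.

#' CNN configuration
#'
#' Defaults: two convolution blocks (16 then 32 filters, kernel 3 x 1,
#' stride 1, same padding), 2 x 1 max pooling with stride 2 after the first
#' block, a 32-unit fully-connected layer, dropout 0.5, a 3-way softmax
#' output, Adam with learning rate 1e-3, 200 epochs, batch size 32. Layer
#' shapes are checked to chain consistently from the length-7 input to the
#' 3-way output.
#'
#' @param input_len Feature-vector length (7).
#' @param conv_filters Filters per convolution block.
#' @param kernel Kernel extent along the length axis (odd).
#' @param pool Pooling `c(extent, stride)` applied after block 1.
#' @param fc_units Units of the hidden fully-connected layer.
#' @param dropout_rate Dropout probability on the hidden FC activations.
#' @param n_classes Number of output classes.
#' @param epochs,learning_rate,batch_size,seed Optimizer settings.
#' @return Object of class `cnn_config`.
#' @export
#' @examples
#' cnn_config(epochs = 10)
cnn_config <- function(input_len = 7, conv_filters = c(16, 32), kernel = 3,
                       pool = c(2, 2), fc_units = 32, dropout_rate = 0.5,
                       n_classes = 3, epochs = 200, learning_rate = 1e-3,
                       batch_size = 32, seed = 1) {
  stopifnot(length(conv_filters) == 2, all(conv_filters >= 1),
            kernel %% 2 == 1, kernel >= 1, length(pool) == 2,
            dropout_rate >= 0, dropout_rate < 1, n_classes >= 2,
            epochs >= 1, learning_rate > 0, batch_size >= 1)
  l1 <- input_len                       # same padding
  lp <- floor((l1 - pool[1]) / pool[2]) + 1
  if (lp < 1) stop("shape mismatch: pooled length < 1")
  if (lp < 1 || l1 < kernel %/% 2 + 1)
    stop("shape mismatch in convolution chain")
  structure(list(input_len = input_len, conv_filters = conv_filters,
                 kernel = kernel, pool = pool, fc_units = fc_units,
                 dropout_rate = dropout_rate, n_classes = n_classes,
                 epochs = epochs, learning_rate = learning_rate,
                 batch_size = batch_size, seed = as.integer(seed),
                 pooled_len = lp, flat_dim = lp * conv_filters[2]),
            class = "cnn_config")
}

# ---- layer primitives (B x L x C arrays; im2col based convolution) -------

conv1d_cols <- function(X3, kernel) {
  d <- dim(X3); B <- d[1]; L <- d[2]; C <- d[3]
  half <- kernel %/% 2
  Xp <- array(0, c(B, L + 2 * half, C))
  Xp[, half + seq_len(L), ] <- X3
  M <- matrix(0, B * L, kernel * C)
  for (u in seq_len(kernel))
    M[, (u - 1) * C + seq_len(C)] <-
      array(Xp[, u:(u + L - 1), , drop = FALSE], c(B * L, C))
  M
}

conv1d_cols_back <- function(dM, dims, kernel) {
  B <- dims[1]; L <- dims[2]; C <- dims[3]
  half <- kernel %/% 2
  dXp <- array(0, c(B, L + 2 * half, C))
  for (u in seq_len(kernel))
    dXp[, u:(u + L - 1), ] <- dXp[, u:(u + L - 1), , drop = FALSE] +
      array(dM[, (u - 1) * C + seq_len(C)], c(B, L, C))
  dXp[, half + seq_len(L), , drop = FALSE]
}

bn_forward <- function(Z, gamma, beta, training, run_mean, run_var,
                       eps = 1e-5) {
  if (training) {
    mu <- colMeans(Z)
    v <- colMeans(sweep(Z, 2, mu)^2)
  } else {
    mu <- run_mean; v <- run_var
  }
  xhat <- sweep(sweep(Z, 2, mu), 2, sqrt(v + eps), "/")
  list(out = sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+"),
       xhat = xhat, mu = mu, v = v, eps = eps)
}

bn_backward <- function(dY, cache, gamma) {
  n <- nrow(dY)
  dxhat <- sweep(dY, 2, gamma, "*")
  dgamma <- colSums(dY * cache$xhat)
  dbeta <- colSums(dY)
  inv_sd <- 1 / sqrt(cache$v + cache$eps)
  dZ <- sweep(dxhat - matrix(colMeans(dxhat), n, ncol(dY), byrow = TRUE) -
                cache$xhat *
                  matrix(colMeans(dxhat * cache$xhat), n, ncol(dY), byrow = TRUE),
              2, inv_sd, "*")
  list(dZ = dZ, dgamma = dgamma, dbeta = dbeta)
}

maxpool_forward <- function(X3, pool) {
  d <- dim(X3); B <- d[1]; L <- d[2]; C <- d[3]
  lp <- floor((L - pool[1]) / pool[2]) + 1
  out <- array(-Inf, c(B, lp, C))
  amax <- array(1L, c(B, lp, C))
  for (t in seq_len(lp)) {
    base <- (t - 1) * pool[2]
    for (u in seq_len(pool[1])) {
      v <- X3[, base + u, , drop = FALSE]
      upd <- v[, 1, ] > out[, t, ]
      out[, t, ][upd] <- v[, 1, ][upd]
      amax[, t, ][upd] <- base + u
    }
  }
  list(out = out, amax = amax, in_dim = d)
}

maxpool_backward <- function(dY, cache) {
  dX <- array(0, cache$in_dim)
  d <- dim(dY)
  for (t in seq_len(d[2])) {
    for (b in seq_len(d[1])) {
      src <- cache$amax[b, t, ]
      for (c in seq_len(d[3]))
        dX[b, src[c], c] <- dX[b, src[c], c] + dY[b, t, c]
    }
  }
  dX
}

cnn_init_params <- function(cfg) {
  f1 <- cfg$conv_filters[1]; f2 <- cfg$conv_filters[2]; k <- cfg$kernel
  he <- function(nr, nc) matrix(rnorm(nr * nc, 0, sqrt(2 / nr)), nr, nc)
  list(W1 = he(k * 1, f1), b1 = numeric(f1),
       g1 = rep(1, f1), be1 = numeric(f1),
       W2 = he(k * f1, f2), b2 = numeric(f2),
       g2 = rep(1, f2), be2 = numeric(f2),
       W3 = he(cfg$flat_dim, cfg$fc_units), b3 = numeric(cfg$fc_units),
       W4 = he(cfg$fc_units, cfg$n_classes), b4 = numeric(cfg$n_classes))
}

cnn_forward <- function(par, cfg, X, training = FALSE, run = NULL,
                        drop_mask = NULL) {
  B <- nrow(X)
  f1 <- cfg$conv_filters[1]; f2 <- cfg$conv_filters[2]
  X3 <- array(X, c(B, cfg$input_len, 1))
  M1 <- conv1d_cols(X3, cfg$kernel)
  Z1 <- sweep(M1 %*% par$W1, 2, par$b1, "+")              # (B*L) x f1
  bn1 <- bn_forward(Z1, par$g1, par$be1, training, run$m1, run$v1)
  A1 <- pmax(bn1$out, 0)
  A13 <- array(A1, c(B, cfg$input_len, f1))
  pl <- maxpool_forward(A13, cfg$pool)
  M2 <- conv1d_cols(pl$out, cfg$kernel)
  Z2 <- sweep(M2 %*% par$W2, 2, par$b2, "+")              # (B*lp) x f2
  bn2 <- bn_forward(Z2, par$g2, par$be2, training, run$m2, run$v2)
  A2 <- pmax(bn2$out, 0)
  Flat <- array(array(A2, c(B, cfg$pooled_len, f2)), c(B, cfg$flat_dim))
  H <- sweep(Flat %*% par$W3, 2, par$b3, "+")
  if (training && cfg$dropout_rate > 0) {
    if (is.null(drop_mask))
      drop_mask <- matrix(rbinom(length(H), 1, 1 - cfg$dropout_rate),
                          nrow(H), ncol(H))
    H <- H * drop_mask / (1 - cfg$dropout_rate)
  }
  logits <- sweep(H %*% par$W4, 2, par$b4, "+")
  probs <- softmax(logits)
  list(probs = probs, cache = list(X3 = X3, M1 = M1, bn1 = bn1, A1 = A1,
                                   pl = pl, M2 = M2, bn2 = bn2, A2 = A2,
                                   Flat = Flat, H = H, drop_mask = drop_mask,
                                   B = B))
}

cnn_backward <- function(par, cfg, fw, Y) {
  ca <- fw$cache
  B <- ca$B
  f1 <- cfg$conv_filters[1]; f2 <- cfg$conv_filters[2]
  dlogits <- (fw$probs - Y) / B
  gW4 <- crossprod(ca$H, dlogits); gb4 <- colSums(dlogits)
  dH <- tcrossprod(dlogits, par$W4)
  if (!is.null(ca$drop_mask))
    dH <- dH * ca$drop_mask / (1 - cfg$dropout_rate)
  gW3 <- crossprod(ca$Flat, dH); gb3 <- colSums(dH)
  dFlat <- tcrossprod(dH, par$W3)
  dA2 <- array(array(dFlat, c(B, cfg$pooled_len, f2)),
               c(B * cfg$pooled_len, f2))
  dA2 <- dA2 * (ca$bn2$out > 0)
  bb2 <- bn_backward(dA2, ca$bn2, par$g2)
  gW2 <- crossprod(ca$M2, bb2$dZ); gb2 <- colSums(bb2$dZ)
  dM2 <- tcrossprod(bb2$dZ, par$W2)
  dPl <- conv1d_cols_back(dM2, c(B, cfg$pooled_len, f1), cfg$kernel)
  dA13 <- maxpool_backward(dPl, ca$pl)
  dA1 <- array(dA13, c(B * cfg$input_len, f1))
  dA1 <- dA1 * (ca$bn1$out > 0)
  bb1 <- bn_backward(dA1, ca$bn1, par$g1)
  gW1 <- crossprod(ca$M1, bb1$dZ); gb1 <- colSums(bb1$dZ)
  list(W1 = gW1, b1 = gb1, g1 = bb1$dgamma, be1 = bb1$dbeta,
       W2 = gW2, b2 = gb2, g2 = bb2$dgamma, be2 = bb2$dbeta,
       W3 = gW3, b3 = gb3, W4 = gW4, b4 = gb4)
}

#' Build and train the CNN classifier
#'
#' Trains with cross-entropy on softmax outputs using Adam, recording the
#' per-epoch training accuracy and loss curves. Features are z-scored with a
#' scaler fit on the training set. Fully deterministic given `config$seed`.
#'
#' @param train Training [feature_table()].
#' @param config A [cnn_config()].
#' @return Object of class `tdpsd_model` (kind `"cnn"`); `$fit$curves` holds
#'   the epoch / accuracy / loss training curves.
#' @export
build_and_train_cnn <- function(train, config = cnn_config()) {
  stopifnot(inherits(train, "feature_table"), inherits(config, "cnn_config"))
  X <- ft_x(train)
  if (ncol(X) != config$input_len)
    stop("config error: input_len does not match the feature dimension")
  y <- train$labels
  scaler <- fit_scaler(X)
  Xs <- apply_scaler(scaler, X)
  n <- nrow(Xs)
  Y <- matrix(0, n, config$n_classes)
  Y[cbind(seq_len(n), y)] <- 1

  set.seed(config$seed)
  par <- cnn_init_params(config)
  run <- list(m1 = numeric(config$conv_filters[1]),
              v1 = rep(1, config$conv_filters[1]),
              m2 = numeric(config$conv_filters[2]),
              v2 = rep(1, config$conv_filters[2]))
  mom <- 0.1
  adam_m <- lapply(par, function(p) p * 0)
  adam_v <- lapply(par, function(p) p * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0
  curves <- data.frame(epoch = integer(0), accuracy = numeric(0),
                       loss = numeric(0))
  for (ep in seq_len(config$epochs)) {
    ord <- sample(n)
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    for (bt in batches) {
      fw <- cnn_forward(par, config, Xs[bt, , drop = FALSE], training = TRUE)
      run$m1 <- (1 - mom) * run$m1 + mom * fw$cache$bn1$mu
      run$v1 <- (1 - mom) * run$v1 + mom * fw$cache$bn1$v
      run$m2 <- (1 - mom) * run$m2 + mom * fw$cache$bn2$mu
      run$v2 <- (1 - mom) * run$v2 + mom * fw$cache$bn2$v
      gr <- cnn_backward(par, config, fw, Y[bt, , drop = FALSE])
      step <- step + 1
      for (nm in names(gr)) {
        adam_m[[nm]] <- b1 * adam_m[[nm]] + (1 - b1) * gr[[nm]]
        adam_v[[nm]] <- b2 * adam_v[[nm]] + (1 - b2) * gr[[nm]]^2
        mhat <- adam_m[[nm]] / (1 - b1^step)
        vhat <- adam_v[[nm]] / (1 - b2^step)
        par[[nm]] <- par[[nm]] - config$learning_rate * mhat / (sqrt(vhat) + eps)
      }
    }
    fw <- cnn_forward(par, config, Xs, training = FALSE, run = run)
    pred <- max.col(fw$probs, ties.method = "first")
    loss <- -mean(log(pmax(fw$probs[cbind(seq_len(n), y)], 1e-15)))
    curves <- rbind(curves, data.frame(epoch = ep,
                                       accuracy = mean(pred == y),
                                       loss = loss))
  }
  fit <- list(par = par, run = run, config = config, scaler = scaler,
              curves = curves)
  structure(list(kind = "cnn", fit = fit, classes = 1:3,
                 meta = list(seed = config$seed)),
            class = "tdpsd_model")
}

cnn_predict <- function(fit, X) {
  Xs <- apply_scaler(fit$scaler, X)
  fw <- cnn_forward(fit$par, fit$config, Xs, training = FALSE, run = fit$run)
  list(labels = max.col(fw$probs, ties.method = "first"), scores = fw$probs)
}
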